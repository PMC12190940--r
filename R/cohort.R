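#' Mean arterial pressure
#'
#' Computes MAP from systolic and diastolic blood pressure readings as
#' \code{SYS/3 + 2 DIA/3}, the standard clinical weighting reflecting the
#' relative duration of diastole in the cardiac cycle.
#'
#' @param sys Systolic pressure in mmHg. Must satisfy \code{sys >= dia > 0}.
#' @param dia Diastolic pressure in mmHg.
#' @return MAP in mmHg; always lies in \code{[dia, sys]}.
#' @examples
#' mean_arterial_pressure(120, 80)
#' @export
mean_arterial_pressure <- function(sys, dia) {
  stopifnot(is.numeric(sys), is.numeric(dia))
  ok <- is.na(sys) | is.na(dia)
  if (any(!ok & (dia <= 0 | sys < dia)))
    stop("mean_arterial_pressure: require sys >= dia > 0")
  sys / 3 + 2 * dia / 3
}

#' Body mass index
#'
#' @param weight Weight in kg, positive.
#' @param height Height in metres, positive.
#' @return BMI in kg/m^2.
#' @examples
#' body_mass_index(60, 1.6)
#' @export
body_mass_index <- function(weight, height) {
  stopifnot(is.numeric(weight), is.numeric(height))
  ok <- is.na(weight) | is.na(height)
  if (any(!ok & (weight <= 0 | height <= 0)))
    stop("body_mass_index: require weight > 0 and height > 0")
  weight / height^2
}

#' Declare a clinical feature
#'
#' A schema entry carries the variable's measurement units, its declared
#' clinical domain (used for partition construction, input validation and
#' clipping of imputed values) and whether it is continuous or a count.
#'
#' @param name Feature name.
#' @param units Measurement units (free text).
#' @param domain_min,domain_max Declared domain bounds, \code{min < max}.
#' @param kind \code{"continuous"} or \code{"count"}. Counts are still
#'   fuzzified like continuous variables.
#' @return A \code{feature_schema} object.
#' @export
feature_schema <- function(name, units = "", domain_min, domain_max,
                           kind = c("continuous", "count")) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(domain_min), is.numeric(domain_max))
  if (!(domain_min < domain_max))
    stop("feature_schema: domain_min must be < domain_max")
  structure(list(name = name, units = units,
                 domain_min = domain_min, domain_max = domain_max,
                 kind = kind),
            class = "feature_schema")
}

#' Default preeclampsia screening schema
#'
#' The five third-trimester variables shared by the source cohorts, with
#' domains set to the published combined-data ranges: mean arterial
#' pressure (MAP, mmHg), body mass index (BMI, kg/m^2), maternal age
#' (years), parity (prior births) and gestational age (GA, weeks).
#'
#' @return Named list of \code{feature_schema} objects.
#' @export
pe_schema <- function() {
  list(
    MAP    = feature_schema("MAP",    "mmHg",   61.66, 140,   "continuous"),
    BMI    = feature_schema("BMI",    "kg/m^2", 16.61, 43.40, "continuous"),
    age    = feature_schema("age",    "years",  18,    45,    "continuous"),
    parity = feature_schema("parity", "births", 1,     6,     "count"),
    GA     = feature_schema("GA",     "weeks",  27.86, 42.42, "continuous")
  )
}

#' Construct a clinical cohort
#'
#' A cohort is the package's tabular container: one row per patient, a
#' numeric value (possibly \code{NA}, the canonical missing marker) per
#' feature, a binary outcome (1 = case/PE, 0 = control/No-PE) that is never
#' missing, and a provenance tag per record.
#'
#' @param data Data frame of numeric feature columns.
#' @param outcome Integer/numeric vector of 0/1 labels, no missing values.
#' @param provenance Character vector of source tags (recycled if length 1).
#' @param schema Optional named list of \code{feature_schema}; when given,
#'   non-missing values are checked against the declared domains.
#' @return A \code{cohort} object.
#' @export
cohort <- function(data, outcome, provenance = "unknown", schema = NULL) {
  data <- as.data.frame(data)
  if (!all(vapply(data, is.numeric, logical(1))))
    stop("cohort: all feature columns must be numeric")
  outcome <- as.integer(outcome)
  if (nrow(data) != length(outcome))
    stop("cohort: outcome length must equal number of records")
  if (anyNA(outcome) || !all(outcome %in% c(0L, 1L)))
    stop("cohort: outcome must be 0/1 and never missing")
  if (length(provenance) == 1L) provenance <- rep(provenance, nrow(data))
  if (length(provenance) != nrow(data))
    stop("cohort: provenance length mismatch")
  if (!is.null(schema)) {
    for (nm in intersect(names(data), names(schema))) {
      s <- schema[[nm]]
      v <- data[[nm]]
      bad <- !is.na(v) & (v < s$domain_min | v > s$domain_max)
      if (any(bad))
        stop(sprintf("cohort: %d value(s) of %s outside declared domain [%g, %g]",
                     sum(bad), nm, s$domain_min, s$domain_max))
    }
  }
  structure(list(data = data, outcome = outcome,
                 provenance = as.character(provenance), schema = schema),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d records x %d features (%s)\n",
              nrow(x$data), ncol(x$data),
              paste(names(x$data), collapse = ", ")))
  cat(sprintf("  outcome: %d positive / %d negative; missing cells: %d\n",
              sum(x$outcome == 1L), sum(x$outcome == 0L),
              sum(is.na(as.matrix(x$data)))))
  invisible(x)
}

#' @export
as.data.frame.cohort <- function(x, ...) {
  cbind(x$data, outcome = x$outcome, provenance = x$provenance,
        stringsAsFactors = FALSE)
}

#' Number of records in a cohort
#' @param x A \code{cohort}.
#' @return Integer count.
#' @export
n_records <- function(x) nrow(x$data)

#' Feature names of a cohort
#' @param x A \code{cohort}.
#' @return Character vector.
#' @export
feature_names <- function(x) names(x$data)

# canonical alias map: lower-cased header -> canonical feature name
.default_aliases <- function() {
  c(map = "MAP", "mean_arterial_pressure" = "MAP",
    bmi = "BMI", "body_mass_index" = "BMI",
    age = "age", "maternal_age" = "age",
    parity = "parity", para = "parity",
    ga = "GA", "gestational_age" = "GA",
    outcome = "outcome", class = "outcome", pe = "outcome", label = "outcome")
}

#' Load a cohort from a delimited text file
#'
#' Reads a comma-delimited table with a header row. Column names are matched
#' case-insensitively through an alias map (so \code{"GA"} and
#' \code{"gestational_age"} are the same variable). Cells that are empty, a
#' common NA spelling, unparseable, or outside the declared schema domain
#' become the canonical missing marker \code{NA}. Outcome values may be
#' \code{0/1} or \code{No-PE/PE}.
#'
#' The returned cohort carries a load report (attribute
#' \code{"load_report"}) counting missing cells per feature.
#'
#' @param path Path to the CSV file.
#' @param schema Named list of \code{feature_schema} (default
#'   \code{pe_schema()}). Only schema features found in the file are kept.
#' @param aliases Named character vector mapping lower-cased headers to
#'   canonical names.
#' @param provenance Source tag stored on every record.
#' @return A \code{cohort} with a \code{"load_report"} attribute.
#' @export
load_cohort <- function(path, schema = pe_schema(),
                        aliases = .default_aliases(),
                        provenance = basename(path)) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  if (nrow(raw) == 0L) stop("load_cohort: empty file")
  canon <- aliases[tolower(trimws(names(raw)))]
  if (!"outcome" %in% canon) stop("load_cohort: no outcome column found")
  na_spellings <- c("", "na", "n/a", "nan", "null", "?", ".", "-")
  parse_num <- function(x) {
    x <- trimws(x)
    x[tolower(x) %in% na_spellings] <- NA
    suppressWarnings(as.numeric(x))
  }
  out_raw <- tolower(trimws(raw[[which(canon == "outcome")[1]]]))
  outcome <- ifelse(out_raw %in% c("1", "pe", "yes", "true"), 1L,
                    ifelse(out_raw %in% c("0", "no-pe", "nope", "no", "false"),
                           0L, NA_integer_))
  if (anyNA(outcome)) stop("load_cohort: unparseable outcome values")
  keep <- names(schema)[names(schema) %in% canon]
  if (length(keep) == 0L) stop("load_cohort: no schema feature found in file")
  data <- as.data.frame(lapply(keep, function(nm) {
    v <- parse_num(raw[[which(canon == nm)[1]]])
    s <- schema[[nm]]
    v[!is.na(v) & (v < s$domain_min | v > s$domain_max)] <- NA
    v
  }))
  names(data) <- keep
  co <- cohort(data, outcome, provenance = provenance,
               schema = schema[keep])
  report <- data.frame(feature = keep,
                       n_missing = vapply(data, function(v) sum(is.na(v)),
                                          integer(1)),
                       row.names = NULL)
  attr(co, "load_report") <- report
  co
}

#' Merge cohorts on their common features
#'
#' Restricts every cohort to the intersection of feature names and stacks
#' the records; provenance tags are preserved. The merge is order-insensitive
#' up to record ordering.
#'
#' @param cohorts List of \code{cohort} objects sharing the outcome
#'   definition.
#' @return A merged \code{cohort}.
#' @export
merge_cohorts <- function(cohorts) {
  stopifnot(is.list(cohorts), length(cohorts) >= 1L)
  if (length(cohorts) == 1L) return(cohorts[[1]])
  feats <- Reduce(intersect, lapply(cohorts, feature_names))
  if (length(feats) == 0L)
    stop("merge_cohorts: empty feature intersection")
  data <- do.call(rbind, lapply(cohorts, function(co) co$data[, feats, drop = FALSE]))
  rownames(data) <- NULL
  schema <- cohorts[[1]]$schema
  if (!is.null(schema)) schema <- schema[intersect(names(schema), feats)]
  cohort(data,
         outcome = unlist(lapply(cohorts, function(co) co$outcome)),
         provenance = unlist(lapply(cohorts, function(co) co$provenance)),
         schema = if (length(schema)) schema else NULL)
}

#' Write a cohort to CSV
#' @param x A \code{cohort}.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_cohort <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, na = "")
  invisible(path)
}
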