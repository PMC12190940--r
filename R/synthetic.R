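#' Specify a synthetic clinical cohort
#'
#' A cohort spec stores, per class and per feature, the marginal mean,
#' standard deviation and range from which records are drawn (independent
#' truncated normals), the class sizes, and optional per-feature missingness
#' rates. Only marginal class-conditional summaries are published for the
#' reference data, so no covariance is modelled.
#'
#' @param class_stats Named list (\code{"0"}, \code{"1"}) of data frames with
#'   columns \code{feature, mean, sd, min, max}.
#' @param counts Named integer vector: records per class, e.g.
#'   \code{c("0" = 502, "1" = 72)}.
#' @param miss_rates Optional named numeric vector of per-feature
#'   missingness rates in \code{[0, 1)}.
#' @param schema Named list of \code{feature_schema} attached to generated
#'   cohorts.
#' @return A \code{cohort_spec} object.
#' @export
cohort_spec <- function(class_stats, counts, miss_rates = NULL,
                        schema = NULL) {
  stopifnot(is.list(class_stats), all(c("0", "1") %in% names(class_stats)))
  for (cs in class_stats) {
    stopifnot(all(c("feature", "mean", "sd", "min", "max") %in% names(cs)))
    if (any(cs$min >= cs$max)) stop("cohort_spec: min must be < max")
    if (any(cs$sd <= 0)) stop("cohort_spec: sd must be > 0")
  }
  counts <- as.integer(counts)
  names(counts) <- c("0", "1")
  if (any(counts < 1L)) stop("cohort_spec: class counts must be >= 1")
  if (!is.null(miss_rates) &&
      (any(miss_rates < 0) || any(miss_rates >= 1)))
    stop("cohort_spec: missingness rates must be in [0, 1)")
  structure(list(class_stats = class_stats, counts = counts,
                 miss_rates = miss_rates, schema = schema),
            class = "cohort_spec")
}

#' Published class-conditional summary spec
#'
#' The default generator spec reproduces the combined multi-ethnic
#' third-trimester dataset's class-conditional marginals: 502 No-PE records
#' (MAP 86.21 +/- 18.70, BMI 23.86 +/- 3.72, age 32.06 +/- 5.27, parity
#' 1.64 +/- 0.82, GA 40.16 +/- 1.17) versus 72 PE records (MAP 113.18 +/-
#' 11.48, BMI 26.25 +/- 3.52, age 27.01 +/- 6.63, parity 1.51 +/- 0.55,
#' GA 38.13 +/- 1.89), each truncated to the published per-class ranges.
#'
#' @return A \code{cohort_spec}.
#' @export
pe_cohort_spec <- function() {
  no_pe <- data.frame(
    feature = c("MAP", "BMI", "age", "parity", "GA"),
    mean = c(86.21, 23.86, 32.06, 1.64, 40.16),
    sd   = c(18.70,  3.72,  5.27, 0.82,  1.17),
    min  = c(61.66, 16.61, 18,    1,    27.86),
    max  = c(133.33, 43.40, 45,   6,    42.42))
  pe <- data.frame(
    feature = c("MAP", "BMI", "age", "parity", "GA"),
    mean = c(113.18, 26.25, 27.01, 1.51, 38.13),
    sd   = c(11.48,  3.52,  6.63, 0.55,  1.89),
    min  = c(72.66, 17.31, 18,    1,    30),
    max  = c(140,   38.36, 43,    3,    41.57))
  cohort_spec(list("0" = no_pe, "1" = pe), c("0" = 502L, "1" = 72L),
              schema = pe_schema())
}

# inverse-CDF truncated normal draw (deterministic given RNG state)
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (mean < lo - 6 * sd || mean > hi + 6 * sd)
    stop("generate_cohort: truncation infeasible (mean > 6 sd outside bounds)")
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  x <- stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
  pmin(pmax(x, lo), hi)
}

#' Generate a synthetic cohort
#'
#' Draws each feature from a class-conditional truncated normal with the
#' spec's mean/sd/bounds. Count features (parity) are rounded to the nearest
#' positive integer. The draw is deterministic for a given seed.
#'
#' @param spec A \code{cohort_spec}.
#' @param seed Integer RNG seed.
#' @return A \code{cohort} with records ordered class 0 then class 1.
#' @export
generate_cohort <- function(spec = pe_cohort_spec(), seed = 123) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)
  blocks <- lapply(c("0", "1"), function(cl) {
    cs <- spec$class_stats[[cl]]
    n <- spec$counts[[cl]]
    cols <- lapply(seq_len(nrow(cs)), function(i) {
      v <- .rtruncnorm(n, cs$mean[i], cs$sd[i], cs$min[i], cs$max[i])
      kind <- if (!is.null(spec$schema) && cs$feature[i] %in% names(spec$schema))
        spec$schema[[cs$feature[i]]]$kind else "continuous"
      if (kind == "count") v <- pmax(1, round(v))
      v
    })
    names(cols) <- cs$feature
    as.data.frame(cols)
  })
  co <- cohort(rbind(blocks[[1]], blocks[[2]]),
               outcome = rep(c(0L, 1L), spec$counts),
               provenance = "synthetic", schema = spec$schema)
  if (!is.null(spec$miss_rates))
    co <- inject_missing(co, spec$miss_rates, seed = seed + 1L)
  co
}

#' Inject missing values completely at random
#'
#' Independently masks feature cells with the given per-feature rates
#' (MCAR). The outcome is never masked. The applied mask is recorded in the
#' \code{"missing_mask"} attribute.
#'
#' @param x A \code{cohort}.
#' @param rates Named numeric vector of rates in \code{[0, 1)}; features not
#'   named are left intact.
#' @param seed Integer RNG seed.
#' @return The masked \code{cohort}.
#' @export
inject_missing <- function(x, rates, seed = 123) {
  stopifnot(inherits(x, "cohort"))
  if (any(rates < 0) || any(rates >= 1))
    stop("inject_missing: rates must be in [0, 1)")
  set.seed(seed)
  mask <- matrix(FALSE, n_records(x), length(feature_names(x)),
                 dimnames = list(NULL, feature_names(x)))
  for (nm in intersect(names(rates), feature_names(x))) {
    if (rates[[nm]] > 0) {
      m <- stats::runif(n_records(x)) < rates[[nm]]
      x$data[[nm]][m] <- NA
      mask[, nm] <- m
    }
  }
  attr(x, "missing_mask") <- mask
  x
}

#' Linearly separable two-feature fixture cohort
#'
#' Two MAP/BMI-like features with disjoint class-conditional MAP bands
#' (controls 70-90 mmHg, cases 105-130 mmHg) and overlapping BMI, so a
#' depth-2 fuzzy tree classifies essentially all training records. Labels
#' are balanced to within one record.
#'
#' @param n Total number of records, \code{>= 20}.
#' @param seed Integer RNG seed.
#' @return A \code{cohort}.
#' @export
make_separable_cohort <- function(n = 100, seed = 123) {
  stopifnot(n >= 20)
  set.seed(seed)
  n0 <- ceiling(n / 2); n1 <- n - n0
  schema <- list(MAP = feature_schema("MAP", "mmHg", 60, 140),
                 BMI = feature_schema("BMI", "kg/m^2", 15, 40))
  data <- data.frame(
    MAP = c(stats::runif(n0, 70, 90), stats::runif(n1, 105, 130)),
    BMI = stats::runif(n, 20, 30))
  cohort(data, outcome = rep(c(0L, 1L), c(n0, n1)),
         provenance = "synthetic", schema = schema)
}
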