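#' Triangular fuzzy set
#'
#' A triangular membership function with support \code{[a, c]} and core
#' (peak) \code{b}. Boundary sets of a strong partition are shouldered:
#' membership stays at 1 beyond the outermost peak, so every real input is
#' fully covered even outside the training range.
#'
#' @param label Linguistic term (e.g. \code{"VL"}, \code{"L"}, \code{"M"},
#'   \code{"H"}).
#' @param a,b,c Left support bound, core and right support bound in the
#'   variable's units; \code{a <= b <= c} and \code{a < c}.
#' @param shoulder \code{"none"}, \code{"left"} (degree 1 for \code{x <= b})
#'   or \code{"right"} (degree 1 for \code{x >= b}).
#' @return A \code{fuzzy_set}.
#' @export
fuzzy_set <- function(label, a, b, c, shoulder = c("none", "left", "right")) {
  shoulder <- match.arg(shoulder)
  if (!(a <= b && b <= c)) stop("fuzzy_set: need a <= b <= c")
  if (!(a < c)) stop("fuzzy_set: degenerate set (a == c) not allowed")
  structure(list(label = label, a = a, b = b, c = c, shoulder = shoulder),
            class = "fuzzy_set")
}

#' Membership degree of a value in a triangular fuzzy set
#'
#' Piecewise-linear triangle: 0 outside \code{[a, c]}, 1 at the core
#' \code{b}, linear in between; shouldered boundary sets return 1 beyond
#' their core.
#'
#' @param set A \code{fuzzy_set}.
#' @param x Numeric vector (may lie outside the support).
#' @return Degrees in \code{[0, 1]}, same length as \code{x}.
#' @export
membership <- function(set, x) {
  stopifnot(inherits(set, "fuzzy_set"))
  up <- if (set$b > set$a) (x - set$a) / (set$b - set$a) else
    as.numeric(x >= set$b)
  dn <- if (set$c > set$b) (set$c - x) / (set$c - set$b) else
    as.numeric(x <= set$b)
  m <- pmax(0, pmin(up, dn, 1))
  if (set$shoulder == "left")  m[x <= set$b] <- 1
  if (set$shoulder == "right") m[x >= set$b] <- 1
  m
}

# canonical linguistic labels by partition size
.linguistic_labels <- function(k) {
  switch(as.character(k),
         "2" = c("L", "H"),
         "3" = c("L", "M", "H"),
         "4" = c("VL", "L", "M", "H"),
         "5" = c("VL", "L", "M", "H", "VH"),
         paste0("T", seq_len(k)))
}

#' Strong triangular fuzzy partition
#'
#' Builds the strong partition defined by a sorted anchor (peak) vector:
#' set \code{i} peaks at \code{anchors[i]} and its support ends at the
#' neighbouring peaks, so the peak of one triangle coincides with the
#' support boundary of its neighbours and memberships sum to one over the
#' anchor span. The first and last sets are shouldered.
#'
#' @param feature Feature name.
#' @param anchors Strictly increasing numeric vector of peaks (length >= 2);
#'   the first/last anchor are the domain bounds of the partition.
#' @param labels Optional character labels (default: canonical VL/L/M/H...).
#' @return A \code{strong_partition}.
#' @export
strong_partition <- function(feature, anchors, labels = NULL) {
  anchors <- as.numeric(anchors)
  k <- length(anchors)
  if (k < 2L) stop("strong_partition: need at least 2 anchors")
  if (any(diff(anchors) <= 0))
    stop("strong_partition: anchors must be strictly increasing")
  if (is.null(labels)) labels <- .linguistic_labels(k)
  if (length(labels) != k) stop("strong_partition: labels/anchors mismatch")
  sets <- lapply(seq_len(k), function(i) {
    fuzzy_set(labels[i],
              a = if (i == 1L) anchors[1] else anchors[i - 1L],
              b = anchors[i],
              c = if (i == k) anchors[k] else anchors[i + 1L],
              shoulder = if (i == 1L) "left" else
                if (i == k) "right" else "none")
  })
  names(sets) <- labels
  structure(list(feature = feature, anchors = anchors, labels = labels,
                 sets = sets),
            class = "strong_partition")
}

#' @export
print.strong_partition <- function(x, ...) {
  cat(sprintf("<strong_partition> %s: %d sets (%s), anchors %s\n",
              x$feature, length(x$sets), paste(x$labels, collapse = "/"),
              paste(signif(x$anchors, 6), collapse = ", ")))
  invisible(x)
}

#' Membership matrix of a partition
#'
#' @param partition A \code{strong_partition}.
#' @param x Numeric vector.
#' @return Matrix \code{length(x)} by number of sets; columns named by
#'   linguistic label. Rows sum to 1 over the anchor span.
#' @export
partition_membership <- function(partition, x) {
  stopifnot(inherits(partition, "strong_partition"))
  m <- vapply(partition$sets, function(s) membership(s, x),
              numeric(length(x)))
  if (length(x) == 1L) m <- matrix(m, nrow = 1L,
                                   dimnames = list(NULL, partition$labels))
  m
}

#' Uniform strong partition over a feature's declared domain
#'
#' Anchors are equally spaced from \code{domain_min} to \code{domain_max}.
#'
#' @param schema A \code{feature_schema}.
#' @param k Number of fuzzy sets, \code{>= 2}.
#' @param labels Optional labels.
#' @return A \code{strong_partition}.
#' @export
uniform_strong_partition <- function(schema, k, labels = NULL) {
  stopifnot(inherits(schema, "feature_schema"))
  if (k < 2L) stop("uniform_strong_partition: k must be >= 2")
  strong_partition(schema$name,
                   seq(schema$domain_min, schema$domain_max, length.out = k),
                   labels)
}

# fuzzy information gain of the strong partition defined by `anchors`
# against the whole sample (parent membership 1 everywhere)
.partition_gain <- function(values, y, anchors) {
  child <- partition_membership(strong_partition("x", anchors), values)
  fuzzy_gain(rep(1, length(values)), child, y)
}

#' Supervised fuzzy discretization of a feature
#'
#' Builds a strong partition by greedy anchor insertion: at each step the
#' candidate anchor whose insertion most increases the fuzzy information
#' gain of the whole partition (against the class labels) is added.
#' Candidate anchors are midpoints between consecutive distinct sorted
#' values; gain ties break toward the leftmost candidate. Insertion stops
#' when the best marginal gain falls below \code{min_gain}, when every
#' current fuzzy set's entropy is below \code{min_impurity}, or (for
#' \code{threshold != 0}) when the partition reaches \code{threshold + 2}
#' sets. The outer anchors are the observed min/max.
#'
#' @param values Numeric feature values (no missing).
#' @param labels Class labels (0/1) aligned with \code{values}.
#' @param min_impurity Minimum fuzzy entropy (bits) a set must have for
#'   refinement to continue.
#' @param min_gain Minimum marginal fuzzy information gain to accept an
#'   anchor.
#' @param threshold Cap parameter: \code{threshold + 2} sets maximum when
#'   non-zero; 0 means no cap.
#' @param feature Feature name recorded on the partition.
#' @return A \code{strong_partition}; a constant feature yields a degenerate
#'   two-set partition (with a warning) by widening the point by one unit.
#' @export
supervised_fuzzy_discretization <- function(values, labels,
                                            min_impurity = 0.005,
                                            min_gain = 0.02,
                                            threshold = 2,
                                            feature = "x") {
  stopifnot(length(values) == length(labels), !anyNA(values))
  y <- as.integer(labels)
  vmin <- min(values); vmax <- max(values)
  if (vmin == vmax) {
    warning("supervised_fuzzy_discretization: constant feature")
    return(strong_partition(feature, c(vmin - 0.5, vmax + 0.5)))
  }
  max_sets <- if (threshold != 0) threshold + 2L else Inf
  sv <- sort(unique(values))
  candidates <- (sv[-1] + sv[-length(sv)]) / 2
  anchors <- c(vmin, vmax)
  gain_now <- .partition_gain(values, y, anchors)
  all_pure <- function(anchors) {
    m <- partition_membership(strong_partition("x", anchors), values)
    ents <- apply(m, 2, function(w) {
      card <- class_cardinalities(w, y)
      if (sum(card) <= 0) 0 else fuzzy_entropy(card)
    })
    all(ents < min_impurity)
  }
  while (length(anchors) < max_sets && length(candidates) > 0L &&
         !all_pure(anchors)) {
    gains <- vapply(candidates, function(t)
      .partition_gain(values, y, sort(c(anchors, t))), numeric(1))
    i <- which.max(gains)            # leftmost on ties
    if (gains[i] - gain_now < min_gain) break
    anchors <- sort(c(anchors, candidates[i]))
    gain_now <- gains[i]
    candidates <- candidates[-i]
  }
  strong_partition(feature, anchors)
}

#' Translate a strong partition to four-parameter trapezoid form
#'
#' Each triangle with peak \code{b_i} becomes \code{(p1, p2, left_width,
#' right_width)} with \code{p1 = p2 = b_i}, \code{left_width} the distance
#' to the previous peak (0 for the first set) and \code{right_width} the
#' distance to the next peak (0 for the last set). The translated form has
#' pointwise identical membership to the original triangles.
#'
#' @param partition A \code{strong_partition}.
#' @return Data frame with columns \code{label, p1, p2, left_width,
#'   right_width}, one row per set.
#' @export
to_trapezoid <- function(partition) {
  stopifnot(inherits(partition, "strong_partition"))
  b <- partition$anchors
  k <- length(b)
  data.frame(label = partition$labels,
             p1 = b, p2 = b,
             left_width = c(0, diff(b)),
             right_width = c(diff(b), 0),
             row.names = NULL)
}

#' Membership under a trapezoid spec row
#'
#' Evaluates the translated four-parameter form (shouldered at the outer
#' sets, like the source triangles); used to verify the translation is
#' membership-preserving.
#'
#' @param p1,p2 Core bounds (equal for translated triangles).
#' @param left_width,right_width Distances to adjacent anchors; a zero
#'   width marks a shouldered boundary side.
#' @param x Numeric vector.
#' @return Degrees in \code{[0, 1]}.
#' @export
trapezoid_membership <- function(p1, p2, left_width, right_width, x) {
  up <- if (left_width > 0) (x - (p1 - left_width)) / left_width else
    rep(1, length(x))
  dn <- if (right_width > 0) ((p2 + right_width) - x) / right_width else
    rep(1, length(x))
  m <- pmax(0, pmin(up, dn, 1))
  if (left_width == 0)  m[x <= p1] <- 1
  if (right_width == 0) m[x >= p2] <- 1
  m
}

#' Write partitions to JSON
#' @param partitions Named list of \code{strong_partition}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_partitions <- function(partitions, path) {
  obj <- lapply(partitions, function(p)
    list(feature = p$feature, labels = p$labels, anchors = p$anchors))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read partitions from JSON
#' @param path JSON file written by \code{write_partitions}.
#' @return Named list of \code{strong_partition}.
#' @export
read_partitions <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- lapply(obj, function(p)
    strong_partition(p$feature, unlist(p$anchors), unlist(p$labels)))
  names(out) <- vapply(out, `[[`, character(1), "feature")
  out
}
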