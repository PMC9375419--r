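#' Construct a cluster-aggregated CRT dataset
#'
#' A `trial_dataset` holds one row per cluster of a two-arm cluster
#' randomised trial with a binary outcome: a cluster label, the arm
#' indicator (0 = control, 1 = intervention), the number of events, and the
#' cluster size. Because the only covariate in all analyses is the
#' cluster-constant arm indicator, these per-cluster totals are sufficient
#' for every estimator in the package: analysing individual-level and
#' aggregated encodings of the same trial gives identical results.
#'
#' @param cluster character vector of unique cluster labels (kept as text,
#'   never parsed numerically).
#' @param arm integer vector of 0/1 arm indicators, constant per cluster.
#' @param events integer vector of event counts, `0 <= events <= size`.
#' @param size integer vector of cluster sizes, `size >= 1`.
#' @return A data frame of class `trial_dataset` with columns
#'   `cluster`, `arm`, `events`, `size`.
#' @examples
#' trial_dataset(c("c1", "c2"), c(0, 1), c(3, 5), c(10, 12))
#' @export
trial_dataset <- function(cluster, arm, events, size) {
  cluster <- as.character(cluster)
  arm <- as.integer(arm)
  events <- as.integer(events)
  size <- as.integer(size)
  out <- data.frame(cluster = cluster, arm = arm, events = events,
                    size = size, stringsAsFactors = FALSE)
  class(out) <- c("trial_dataset", "data.frame")
  validate_trial_dataset(out)
  out
}

#' Validate the invariants of a trial dataset
#'
#' Checks uniqueness of cluster labels, binary arm coding, and
#' `0 <= events <= size`, `size >= 1`.
#'
#' @param x a `trial_dataset` (or data frame with the same columns).
#' @return `x`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_trial_dataset <- function(x) {
  need <- c("cluster", "arm", "events", "size")
  if (!all(need %in% names(x)))
    stop("trial dataset must have columns cluster, arm, events, size")
  if (nrow(x) == 0) return(invisible(x))
  if (anyDuplicated(x$cluster))
    stop("duplicate cluster id: cluster labels must be unique")
  if (!all(x$arm %in% c(0L, 1L)))
    stop("arm must be coded 0 (control) / 1 (intervention)")
  if (any(x$size < 1L)) stop("cluster size must be >= 1")
  if (any(x$events < 0L) || any(x$events > x$size))
    stop("events must satisfy 0 <= events <= size")
  invisible(x)
}

# error if an analysis needs both arms with at least `min_per_arm` clusters
check_two_arms <- function(data, min_per_arm = 1L) {
  n0 <- sum(data$arm == 0L)
  n1 <- sum(data$arm == 1L)
  if (n0 < min_per_arm || n1 < min_per_arm)
    stop("analysis requires at least ", min_per_arm,
         " cluster(s) per arm (got ", n0, " control, ", n1, " intervention)")
  invisible(data)
}

# map arbitrary two-level arm labels to 0/1
map_arms <- function(arm, control = NULL) {
  lab <- as.character(arm)
  lev <- sort(unique(lab))
  if (length(lev) > 2) stop("more than two arm labels found: ",
                            paste(lev, collapse = ", "))
  if (is.null(control)) control <- lev[1] else control <- as.character(control)
  if (length(lev) && !control %in% lev)
    stop("control label '", control, "' not present in data")
  as.integer(lab != control)
}

#' Read an individual-level CRT file
#'
#' Reads delimited text with header columns `cluster`, `arm`, `outcome`
#' (one row per individual, outcome 0/1) and aggregates to one record per
#' cluster. Any two distinct arm labels are accepted; `control` selects
#' which is coded 0 (default: the lexicographically smaller label).
#'
#' @param path file path.
#' @param sep field separator, `","` (default) or `"\t"`.
#' @param control label of the control arm, or `NULL` for the
#'   lexicographically smaller label.
#' @return A [trial_dataset()].
#' @export
read_trial_individual <- function(path, sep = ",", control = NULL) {
  raw <- read.csv(path, sep = sep, colClasses = "character",
                  check.names = TRUE)
  need <- c("cluster", "arm", "outcome")
  if (!all(need %in% names(raw)))
    stop("individual-level file needs header columns cluster, arm, outcome")
  if (nrow(raw) == 0)
    return(trial_dataset(character(), integer(), integer(), integer()))
  y <- suppressWarnings(as.numeric(raw$outcome))
  if (any(is.na(y)) || !all(y %in% c(0, 1)))
    stop("outcome must be binary 0/1")
  arm01 <- map_arms(raw$arm, control)
  per_cluster_arms <- tapply(arm01, raw$cluster, function(a) length(unique(a)))
  if (any(per_cluster_arms > 1))
    stop("arm varies within a cluster: CRTs randomise whole clusters")
  cl <- sort(unique(raw$cluster))
  events <- as.integer(tapply(y, raw$cluster, sum)[cl])
  size <- as.integer(tapply(y, raw$cluster, length)[cl])
  arm <- as.integer(tapply(arm01, raw$cluster, function(a) a[1])[cl])
  trial_dataset(cl, arm, events, size)
}

#' Read a cluster-aggregated CRT file
#'
#' Reads delimited text with header columns `cluster`, `arm`, `events`,
#' `size` (one row per cluster).
#'
#' @inheritParams read_trial_individual
#' @return A [trial_dataset()].
#' @export
read_trial_aggregated <- function(path, sep = ",", control = NULL) {
  raw <- read.csv(path, sep = sep, colClasses = "character")
  need <- c("cluster", "arm", "events", "size")
  if (!all(need %in% names(raw)))
    stop("aggregated file needs header columns cluster, arm, events, size")
  if (nrow(raw) == 0)
    return(trial_dataset(character(), integer(), integer(), integer()))
  events <- suppressWarnings(as.numeric(raw$events))
  size <- suppressWarnings(as.numeric(raw$size))
  if (any(is.na(events)) || any(is.na(size)))
    stop("events and size must be numeric")
  trial_dataset(raw$cluster, map_arms(raw$arm, control), events, size)
}

#' Write a trial dataset in the aggregated format
#'
#' Emits exactly the columns `cluster,arm,events,size`; reading the file
#' back with [read_trial_aggregated()] recovers the dataset.
#'
#' @param data a [trial_dataset()].
#' @param path output file path.
#' @param sep field separator, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_trial_aggregated <- function(data, path, sep = ",") {
  validate_trial_dataset(data)
  write.table(as.data.frame(data)[, c("cluster", "arm", "events", "size")],
              path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat("Two-arm CRT:", nrow(x), "clusters (",
      sum(x$arm == 0), "control /", sum(x$arm == 1), "intervention ),",
      sum(x$size), "individuals,", sum(x$events), "events\n")
  print.data.frame(x, ...)
  invisible(x)
}
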