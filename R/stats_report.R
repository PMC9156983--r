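#' Average repeated measurements per animal
#'
#' Repeated within-animal measurements (multiple sections, multiple
#' lacunae) are averaged so each animal contributes a single value to the
#' group comparison.
#'
#' @param measurements data frame with columns `animal_id` and `value`,
#'   or two vectors via `animal_id` and `value`.
#' @param animal_id,value used when `measurements` is missing.
#' @return data frame with one row per distinct animal: `animal_id`,
#'   `value` (the arithmetic mean) and `n` (measurement count).
#' @examples
#' aggregatePerAnimal(animal_id = c("A", "A", "B"), value = c(2, 4, 6))
#' @export
aggregatePerAnimal <- function(measurements = NULL, animal_id = NULL,
                               value = NULL) {
  if (is.null(measurements))
    measurements <- data.frame(animal_id = animal_id, value = value)
  if (!nrow(measurements))
    stop("no measurements given", call. = FALSE)
  if (anyNA(measurements$value))
    stop("measurements must not contain NA", call. = FALSE)
  agg <- stats::aggregate(value ~ animal_id, data = measurements,
                          FUN = mean)
  n <- stats::aggregate(value ~ animal_id, data = measurements,
                        FUN = length)
  data.frame(animal_id = agg$animal_id, value = agg$value, n = n$value)
}

#' Unpaired two-tailed Student's t-test
#'
#' Equal-variance (pooled SD) two-sample t-test with
#' `df = n1 + n2 - 2`, as used for all group comparisons; Welch's
#' correction is deliberately not applied. The degenerate case of zero
#' pooled variance returns `t = 0, p = 1` for equal means and
#' `t = +/-Inf, p = 0` otherwise.
#'
#' @param group1,group2 numeric vectors, each of length `>= 2`.
#' @param alpha significance level (default 0.05).
#' @return list with `t_statistic`, `df`, `p_value`, `significant`.
#' @examples
#' studentsT(c(1, 2, 3, 4), c(3, 4, 5, 6))
#' @export
studentsT <- function(group1, group2, alpha = 0.05) {
  n1 <- length(group1); n2 <- length(group2)
  if (n1 < 2 || n2 < 2)
    stop("each group needs at least two values", call. = FALSE)
  df <- n1 + n2 - 2
  pooled <- ((n1 - 1) * stats::var(group1) +
             (n2 - 1) * stats::var(group2)) / df
  if (pooled <= 0) {
    delta <- mean(group1) - mean(group2)
    t <- if (delta == 0) 0 else sign(delta) * Inf
    p <- if (delta == 0) 1 else 0
  } else {
    res <- stats::t.test(group1, group2, var.equal = TRUE)
    t <- unname(res$statistic)
    p <- res$p.value
  }
  list(t_statistic = t, df = df, p_value = p,
       significant = p < alpha)
}

#' Boxplot-style five-number summary with mean
#'
#' Quartiles use linear interpolation (the inclusive method,
#' `quantile(type = 7)`); whiskers are the data extremes — no outlier
#' fencing.
#'
#' @param values numeric vector, length `>= 1`, no NA.
#' @return list with `min`, `q25`, `median`, `q75`, `max`, `mean`, `n`.
#' @examples
#' boxplotSummary(1:5)
#' @export
boxplotSummary <- function(values) {
  if (!length(values)) stop("empty input", call. = FALSE)
  if (anyNA(values)) stop("values must not contain NA", call. = FALSE)
  q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
  list(min = min(values), q25 = q[1], median = q[2], q75 = q[3],
       max = max(values), mean = mean(values), n = length(values))
}

#' Two-group comparison report for named metrics
#'
#' For each metric, summarizes both groups ([boxplotSummary()]) and runs
#' the pooled-variance t-test ([studentsT()]); writable as JSON.
#'
#' @param groupA,groupB data frames of per-animal metric values (one
#'   column per metric, one row per animal).
#' @param alpha significance level.
#' @param path optional JSON output path.
#' @return named list, per metric: `summaryA`, `summaryB`, `tTest`.
#' @export
compareGroups <- function(groupA, groupB, alpha = 0.05, path = NULL) {
  metrics <- intersect(names(groupA), names(groupB))
  if (!length(metrics)) stop("no shared metrics", call. = FALSE)
  rep <- lapply(metrics, function(m) {
    list(summaryA = boxplotSummary(groupA[[m]]),
         summaryB = boxplotSummary(groupB[[m]]),
         tTest = studentsT(groupA[[m]], groupB[[m]], alpha))
  })
  names(rep) <- metrics
  if (!is.null(path))
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  rep
}
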