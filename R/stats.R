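# Group-level statistics: per-animal aggregation, unpaired t-test, variance
# F-test, and the two-group comparison with the animal/vessel
# unit-of-analysis switch.

#' Aggregate vessel metrics to one value per animal
#'
#' For each metric column, the unweighted mean over that animal's *included*
#' vessels (the diameter filter's `included` flag; vessels failing it do not
#' contribute). Animals with zero included vessels are dropped with a warning.
#'
#' @param vessel_table data.frame with columns `group`, `animal_id`,
#'   `included`, plus numeric metric columns.
#' @param metrics character vector of metric column names; default: every
#'   numeric column except bookkeeping ones.
#' @return data.frame with one row per animal: `group`, `animal_id`, and the
#'   per-animal means.
#' @export
per_animal_aggregate <- function(vessel_table, metrics = NULL) {
  need <- c("group", "animal_id", "included")
  if (!all(need %in% names(vessel_table))) {
    stop("`vessel_table` needs columns: ", paste(need, collapse = ", "))
  }
  if (is.null(metrics)) {
    metrics <- setdiff(
      names(vessel_table)[vapply(vessel_table, is.numeric, logical(1))],
      c("vessel_id", "included", "seed"))
  }
  dropped <- unique(vessel_table$animal_id[
    !vessel_table$animal_id %in% vessel_table$animal_id[vessel_table$included]])
  if (length(dropped) > 0) {
    warning("animal(s) with zero included vessels dropped: ",
            paste(dropped, collapse = ", "))
  }
  tab <- vessel_table[vessel_table$included, , drop = FALSE]
  if (nrow(tab) == 0) stop("no included vessels")
  agg <- aggregate(tab[metrics], by = list(group = tab$group,
                                           animal_id = tab$animal_id), mean)
  agg[order(agg$group, agg$animal_id), , drop = FALSE]
}

#' Two-sample unpaired t-test
#'
#' Two-sided; pooled-variance (equal-variance) form by default, Welch with
#' `welch = TRUE`. If both groups have zero variance and equal means the
#' conventional result `t = 0, p = 1` is returned (base `t.test()` errors on
#' constant data).
#'
#' @param samples_a,samples_b numeric vectors, each of length >= 2.
#' @param welch use the Welch form (default FALSE).
#' @return list with `t_statistic`, `p_value`, `df`, `mean_a`, `mean_b`,
#'   `welch`.
#' @export
unpaired_t_test <- function(samples_a, samples_b, welch = FALSE) {
  stopifnot(length(samples_a) >= 2, length(samples_b) >= 2,
            all(is.finite(samples_a)), all(is.finite(samples_b)))
  va <- var(samples_a); vb <- var(samples_b)
  if (va == 0 && vb == 0) {
    if (mean(samples_a) == mean(samples_b)) {
      return(list(t_statistic = 0, p_value = 1,
                  df = length(samples_a) + length(samples_b) - 2,
                  mean_a = mean(samples_a), mean_b = mean(samples_b),
                  welch = welch))
    }
    return(list(t_statistic = Inf, p_value = 0,
                df = length(samples_a) + length(samples_b) - 2,
                mean_a = mean(samples_a), mean_b = mean(samples_b),
                welch = welch))
  }
  ht <- t.test(samples_a, samples_b, var.equal = !welch)
  list(t_statistic = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter), mean_a = mean(samples_a),
       mean_b = mean(samples_b), welch = welch)
}

#' Two-sided F-test for equality of variances
#'
#' `F = var(a) / var(b)` with `(n_a - 1, n_b - 1)` degrees of freedom and a
#' two-sided p-value from the F distribution. Zero variance in either group is
#' a named error (`vesselqpi_zero_variance`).
#'
#' @param samples_a,samples_b numeric vectors, each of length >= 2.
#' @return list with `f_statistic`, `p_value`, `df`.
#' @export
variance_f_test <- function(samples_a, samples_b) {
  stopifnot(length(samples_a) >= 2, length(samples_b) >= 2,
            all(is.finite(samples_a)), all(is.finite(samples_b)))
  if (var(samples_a) == 0 || var(samples_b) == 0) {
    stop(structure(
      class = c("vesselqpi_zero_variance", "error", "condition"),
      list(message = "zero variance in one of the groups", call = sys.call())))
  }
  ht <- var.test(samples_a, samples_b)
  list(f_statistic = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter))
}

#' Compare one metric between two groups
#'
#' Runs [per_animal_aggregate()] first when `unit = "animal"` (each animal's
#' mean over its included vessels is one independent observation) or treats
#' each included vessel as independent when `unit = "vessel"`, then applies
#' the unpaired t-test on the means and the F-test on the variances. No
#' multiple-testing correction is applied (a Benjamini-Hochberg step can be
#' added downstream; see the package vignette).
#'
#' @param vessel_table data.frame with `group`, `animal_id`, `vessel_id`,
#'   `included`, and the metric column.
#' @param metric metric column name (e.g. `"mean_thickness"`).
#' @param unit `"animal"` (default) or `"vessel"`.
#' @param alpha significance level (default 0.05).
#' @param welch use the Welch t form (default FALSE).
#' @param histogram_breaks passed to [hist()] for the histogram data
#'   (default `"Sturges"`).
#' @return an object of class `"group_comparison"`.
#' @export
compare_groups <- function(vessel_table, metric, unit = c("animal", "vessel"),
                           alpha = 0.05, welch = FALSE,
                           histogram_breaks = "Sturges") {
  unit <- match.arg(unit)
  groups <- unique(vessel_table$group)
  if (length(groups) != 2) stop("exactly two groups are required")
  if (!metric %in% names(vessel_table)) stop("no such metric: ", metric)
  tab <- if (unit == "animal") {
    per_animal_aggregate(vessel_table, metrics = metric)
  } else {
    vessel_table[vessel_table$included, c("group", "animal_id", metric)]
  }
  a <- tab[tab$group == groups[1], metric]
  b <- tab[tab$group == groups[2], metric]
  if (length(a) < 2 || length(b) < 2) {
    stop("fewer than 2 units in a group (unit = ", unit, ")")
  }
  tt <- unpaired_t_test(a, b, welch = welch)
  ft <- tryCatch(variance_f_test(a, b), vesselqpi_zero_variance = function(e) {
    list(f_statistic = NA_real_, p_value = NA_real_, df = NULL)
  })
  h <- hist(c(a, b), breaks = histogram_breaks, plot = FALSE)
  structure(
    list(group_a = groups[1], group_b = groups[2], unit = unit,
         metric = metric, n_a = length(a), n_b = length(b),
         mean_a = mean(a), mean_b = mean(b), sd_a = sd(a), sd_b = sd(b),
         t_statistic = tt$t_statistic, t_p_value = tt$p_value,
         f_statistic = ft$f_statistic, f_p_value = ft$p_value,
         alpha = alpha, significant = isTRUE(tt$p_value < alpha),
         welch = welch,
         histogram = list(breaks = h$breaks,
                          counts_a = hist(a, breaks = h$breaks, plot = FALSE)$counts,
                          counts_b = hist(b, breaks = h$breaks, plot = FALSE)$counts),
         samples = list(a = a, b = b)),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: %s vs %s (unit = %s)\n",
              x$metric, x$group_a, x$group_b, x$unit))
  cat(sprintf("  n = %d / %d, mean = %.4g / %.4g\n",
              x$n_a, x$n_b, x$mean_a, x$mean_b))
  cat(sprintf("  t = %.3f, p = %.4g%s\n", x$t_statistic, x$t_p_value,
              if (x$significant) " *" else ""))
  if (is.finite(x$f_statistic)) {
    cat(sprintf("  F = %.3f, p = %.4g (variances)\n",
                x$f_statistic, x$f_p_value))
  }
  invisible(x)
}

#' @importFrom stats var
NULL
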