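# Diversity and specificity metrics over registered shape populations, their
# empirical distributions, distribution comparison, and detection of failed
# generations via background-mask IoU.

#' Diversity of a pair of scans
#'
#' The weighted RMSE between the corresponding vertices of a random pair of
#' scans, by default after rigid alignment of the second onto the first.
#' Measures the heterogeneity of a shape set.
#'
#' @param m1,m2 Comparable [registered_mesh()]es.
#' @param w Optional [vertex_weights()] (uniform default).
#' @param align Rigidly align `m2` onto `m1` first (default `TRUE`).
#' @return Distance in mm.
#' @export
diversity <- function(m1, m2, w = NULL, align = TRUE) {
  check_comparable(m1, m2)
  if (align) m2 <- rigid_align(m2, m1, w)$aligned
  weighted_rmse(m1, m2, w)
}

#' Specificity of a synthetic scan
#'
#' Minimum (optionally rigidly aligned) weighted RMSE from the scan to any
#' scan of the training set: how close a generated shape stays to the real
#' population (0 = an exact copy).
#'
#' @param m A [registered_mesh()].
#' @param training Non-empty list of comparable training meshes.
#' @param w Optional [vertex_weights()].
#' @param align Rigidly align before each distance (default `TRUE`).
#' @return Distance in mm.
#' @export
specificity <- function(m, training, w = NULL, align = TRUE) {
  if (!length(training)) stop_arg("empty training list")
  min(vapply(training, function(t) diversity(m, t, w, align), 0))
}

metric_distribution <- function(metric, values, provenance = "test") {
  structure(list(metric = metric, values = as.numeric(values),
                 n = length(values), provenance = provenance),
            class = "metric_distribution")
}

#' @export
print.metric_distribution <- function(x, ...) {
  cat(sprintf("%s distribution (%s): n = %d, median = %.3f mm, IQR = %.3f mm\n",
              x$metric, x$provenance, x$n, stats::median(x$values),
              stats::IQR(x$values)))
  invisible(x)
}

#' Empirical diversity distribution of a shape set
#'
#' Draws `n_pairs` distinct unordered pairs uniformly without replacement
#' and evaluates [diversity()] on each.
#'
#' @param meshes List of >= 2 comparable meshes.
#' @param n_pairs Number of pairs (at most `choose(n, 2)`).
#' @param w,align Passed to [diversity()].
#' @param seed Integer seed.
#' @param provenance Label (`"test"`, `"pca"`, `"vq"`, ...).
#' @return A `metric_distribution`.
#' @export
diversity_distribution <- function(meshes, n_pairs, w = NULL, align = TRUE,
                                   seed = 1L, provenance = "test") {
  n <- length(meshes)
  if (n < 2L) stop_arg("need at least 2 meshes")
  total <- n * (n - 1) / 2
  if (n_pairs > total) stop_arg("n_pairs = %d exceeds %d distinct pairs", n_pairs, total)
  with_seed(seed, {
    pick <- sample.int(total, n_pairs)         # unordered pair ids, no repeats
    # Invert the triangular pair index: pairs (i, j), i < j.
    j <- ceiling((1 + sqrt(1 + 8 * pick)) / 2)
    i <- pick - (j - 1) * (j - 2) / 2
    vals <- vapply(seq_len(n_pairs), function(t)
      diversity(meshes[[i[t]]], meshes[[j[t]]], w, align), 0)
    metric_distribution("diversity", vals, provenance)
  })
}

#' Empirical specificity distribution of a sample set
#'
#' One [specificity()] value per sample against the training set.
#'
#' @param samples List of sampled meshes.
#' @param training Non-empty list of training meshes.
#' @param w,align Passed to [specificity()].
#' @param provenance Label.
#' @return A `metric_distribution`.
#' @export
specificity_distribution <- function(samples, training, w = NULL, align = TRUE,
                                     provenance = "test") {
  if (!length(samples)) stop_arg("empty sample list")
  vals <- vapply(samples, function(m) specificity(m, training, w, align), 0)
  metric_distribution("specificity", vals, provenance)
}

#' Compare two metric distributions
#'
#' Two-sample Kolmogorov-Smirnov statistic and p-value plus a quantile
#' summary table; quantifies whether two sets of scans are statistically
#' close in a metric.
#'
#' @param a,b `metric_distribution`s of the same metric.
#' @return List with `ks_statistic`, `p_value`, and `summary` (data.frame of
#'   quantiles per distribution).
#' @export
compare_distributions <- function(a, b) {
  if (a$metric != b$metric)
    stop_arg("cannot compare %s with %s distributions", a$metric, b$metric)
  ks <- suppressWarnings(stats::ks.test(a$values, b$values))
  qs <- c(0.05, 0.25, 0.5, 0.75, 0.95)
  summary <- data.frame(
    provenance = c(a$provenance, b$provenance),
    n = c(a$n, b$n),
    rbind(stats::quantile(a$values, qs), stats::quantile(b$values, qs)),
    check.names = FALSE
  )
  list(ks_statistic = unname(ks$statistic), p_value = ks$p.value, summary = summary)
}

#' Detect a failed generation from its background mask
#'
#' A sampled geometric image fails when its background pixels are not
#' synthesized where the template has background. Background pixels of the
#' sample are those whose channels all lie within `eps` of the background
#' constant (0 in normalized space); the IoU of that mask against the
#' template background mask flags the failure.
#'
#' @param image A normalized [geometric_image()].
#' @param template_mask `H x W` logical FOREGROUND mask of the template.
#' @param eps Background tolerance (default 1/255, the 8-bit quantum).
#' @param iou_threshold Failure threshold on the background IoU.
#' @return List with `failed` flag and `iou`.
#' @export
detect_failed_sample <- function(image, template_mask, eps = 1 / 255,
                                 iou_threshold = 0.95) {
  if (!identical(dim(template_mask), dim(image$pixels)[1:2]))
    stop_arg("template mask dimensions differ from image")
  bg_sample <- apply(abs(image$pixels) <= eps, c(1, 2), all)
  bg_template <- !template_mask
  inter <- sum(bg_sample & bg_template)
  uni <- sum(bg_sample | bg_template)
  iou <- if (uni == 0L) 1.0 else inter / uni
  list(failed = iou < iou_threshold, iou = iou)
}

#' Export metric distributions as a tidy CSV
#'
#' One value per row with its metric and provenance labels.
#'
#' @param dists List of `metric_distribution`s.
#' @param path Output CSV path.
#' @return The combined data.frame, invisibly.
#' @export
write_metric_csv <- function(dists, path) {
  tab <- do.call(rbind, lapply(dists, function(d)
    data.frame(metric = d$metric, provenance = d$provenance, value = d$values)))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}

#' Overlaid histograms of metric distributions
#'
#' @param dists List of `metric_distribution`s of one metric.
#' @param main Plot title.
#' @param breaks Histogram breaks (passed to [graphics::hist()]).
#' @return Invisibly, `NULL`.
#' @export
plot_metric_distributions <- function(dists, main = NULL, breaks = 20) {
  metric <- dists[[1]]$metric
  all_vals <- unlist(lapply(dists, function(d) d$values))
  brk <- pretty(range(all_vals), breaks)
  cols <- grDevices::hcl.colors(length(dists), "Dark 3", alpha = 0.5)
  for (i in seq_along(dists)) {
    h <- graphics::hist(dists[[i]]$values, breaks = brk, plot = FALSE)
    if (i == 1L)
      plot(h, col = cols[i], main = main %||% sprintf("%s distributions", metric),
           xlab = sprintf("%s (mm)", metric))
    else plot(h, col = cols[i], add = TRUE)
  }
  graphics::legend("topright", legend = vapply(dists, function(d) d$provenance, ""),
                   fill = cols, bty = "n")
  invisible(NULL)
}
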