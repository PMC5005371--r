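#' Response magnitude of the drought treatment per provenance
#'
#' For each individual, the index is averaged over the stress window; the
#' response magnitude is then the pairwise difference between every drought
#' individual and every control individual *within the same provenance*
#' (within-provenance pairing is what allows provenances to be compared by
#' rank tests afterwards). Trees with fewer than `min_days` observed days
#' in the window are dropped with a warning, as are provenances lacking
#' either treatment group.
#'
#' @param obs observation table.
#' @param index response column, `"cwsi"` or `"ig"`.
#' @param window a [period_window()]; the stress window by default.
#' @param min_days minimum measuring days per tree mean; default 3.
#' @return data.frame with `provenance`, `drought_tree_id`,
#'   `control_tree_id`, `delta` (drought mean minus control mean).
#' @export
response_magnitude <- function(obs, index = c("cwsi", "ig"),
                               window = period_window("stress"),
                               min_days = 3L) {
  index <- match.arg(index)
  stopifnot(inherits(window, "period_window"))
  check_columns(obs, c("tree_id", "provenance", "treatment", "day", index))
  sub <- obs[obs$day %in% window$days, , drop = FALSE]
  if (nrow(sub) == 0L) stop("window contains no observations")
  agg <- stats::aggregate(sub[[index]],
                          by = list(tree_id = sub$tree_id,
                                    provenance = sub$provenance,
                                    treatment = sub$treatment),
                          FUN = mean)
  names(agg)[4] <- "mean_index"
  counts <- stats::aggregate(sub[[index]],
                             by = list(tree_id = sub$tree_id),
                             FUN = length)
  short <- counts$tree_id[counts$x < min_days]
  if (length(short)) {
    warning(sprintf("dropping %d tree(s) with fewer than %d days in the window",
                    length(short), min_days))
    agg <- agg[!agg$tree_id %in% short, , drop = FALSE]
  }
  out <- list()
  for (p in unique(agg$provenance)) {
    d <- agg[agg$provenance == p & agg$treatment == "drought", ]
    c_ <- agg[agg$provenance == p & agg$treatment == "control", ]
    if (nrow(d) == 0L || nrow(c_) == 0L) {
      warning("provenance ", p, " lacks one treatment group; excluded")
      next
    }
    grid <- expand.grid(di = seq_len(nrow(d)), ci = seq_len(nrow(c_)))
    out[[p]] <- data.frame(provenance = p,
                           drought_tree_id = d$tree_id[grid$di],
                           control_tree_id = c_$tree_id[grid$ci],
                           delta = d$mean_index[grid$di] -
                             c_$mean_index[grid$ci])
  }
  if (length(out) == 0L) stop("no provenance has both treatment groups")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Kruskal-Wallis test with Dunn's pairwise comparisons
#'
#' Rank-based one-way comparison of several groups (e.g. response
#' magnitudes per provenance): the Kruskal-Wallis H statistic with tie
#' correction (via [stats::kruskal.test()]) followed by Dunn's pairwise z
#' tests on mean ranks,
#' \deqn{z_{ij} = (\bar R_i - \bar R_j) / \sqrt{(\frac{N(N+1)}{12} - C)(\frac{1}{n_i}+\frac{1}{n_j})}}
#' with the tie correction \eqn{C = \sum(t^3 - t) / (12 (N - 1))}, and
#' Benjamini-Hochberg adjustment of the pairwise p-values.
#'
#' @param groups named list mapping group label to numeric sample (each of
#'   size >= 2), or a data.frame with columns `value` and `group`.
#' @return list with `kruskal` (`statistic`, `df`, `p_value`) and
#'   `pairwise` (data.frame: `level_a`, `level_b`, `z`, `p`, `p_adj`).
#' @export
kruskal_dunn <- function(groups) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("value", "group") %in% names(groups)))
    groups <- split(groups$value, groups$group)
  }
  if (length(groups) < 2L) stop("need at least two groups")
  sizes <- lengths(groups)
  if (any(sizes < 2L))
    stop("every group needs at least 2 observations; too small: ",
         paste(names(groups)[sizes < 2L], collapse = ", "))
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), sizes), levels = names(groups))
  kw <- stats::kruskal.test(x, g)

  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  ties <- table(x)
  C <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(names(groups), 2)
  z <- apply(pairs, 2, function(pr) {
    (rbar[[pr[1]]] - rbar[[pr[2]]]) /
      sqrt((N * (N + 1) / 12 - C) * (1 / sizes[[pr[1]]] + 1 / sizes[[pr[2]]]))
  })
  p <- 2 * stats::pnorm(-abs(z))
  list(kruskal = list(statistic = unname(kw$statistic),
                      df = unname(kw$parameter),
                      p_value = unname(kw$p.value)),
       pairwise = data.frame(level_a = pairs[1, ], level_b = pairs[2, ],
                             z = z, p = p,
                             p_adj = stats::p.adjust(p, method = "BH"),
                             row.names = NULL))
}
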