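#' R-statistic for target prioritization
#'
#' Ranks candidate targets of a multi-component preparation by combining two
#' topological parameters of the PPI network with equal weight: the average
#' shortest path length \eqn{X_i} (small = central) and the betweenness
#' centrality \eqn{X_j} (large = central, entered through its reciprocal).
#' Both terms are min-max scaled over the cohort supplied, so
#' \deqn{R = w \frac{X_i - \min X_i}{\max X_i - \min X_i} +
#'        (1-w) \frac{1/X_j - \min(1/X_j)}{\max(1/X_j) - \min(1/X_j)}}
#' with \eqn{w = 0.5} by default. Smaller R means a more important target;
#' the record attaining both the minimum \eqn{X_i} and maximum \eqn{X_j}
#' scores exactly 0. Betweenness values below `xj_floor` are clamped to it
#' before taking reciprocals (the statistic is undefined at 0).
#'
#' If all cohort values coincide on one axis, that term contributes 0 for
#' every record.
#'
#' @param targets data frame with numeric columns `avg_shortest_path` and
#'   `betweenness` (one row per target); other columns pass through.
#' @param weight_xi weight on the path-length term, in [0, 1]; the
#'   betweenness term gets `1 - weight_xi`.
#' @param xj_floor positive clamp applied to `betweenness` before 1/xj.
#' @return the input with an `r` column appended.
#' @export
r_score <- function(targets, weight_xi = 0.5, xj_floor = 1e-5) {
  stopifnot(is.data.frame(targets),
            all(c("avg_shortest_path", "betweenness") %in% names(targets)))
  if (nrow(targets) < 2L) stop("need at least 2 targets to min-max scale")
  xi <- targets$avg_shortest_path
  if (any(!is.finite(xi)) || any(xi <= 0)) {
    stop("avg_shortest_path must be positive and finite for all targets")
  }
  if (weight_xi < 0 || weight_xi > 1) stop("weight_xi must lie in [0, 1]")
  if (xj_floor <= 0) stop("xj_floor must be positive")
  xj <- pmax(targets$betweenness, xj_floor)
  inv <- 1 / xj
  scale01 <- function(v) {
    rng <- max(v) - min(v)
    if (rng == 0) rep(0, length(v)) else (v - min(v)) / rng
  }
  targets$r <- weight_xi * scale01(xi) + (1 - weight_xi) * scale01(inv)
  targets
}

#' Rank targets by R score
#'
#' Orders a scored cohort ascending by `r` (smaller = more important) and
#' returns the top `k`. Ties are broken by larger betweenness, then by
#' accession (or the first column) lexicographically, so the ordering is
#' deterministic. An optional `status` filter restricts the cohort to
#' validated or predicted targets *before* taking the top `k` (scores are
#' not recomputed: the cohort that defined the min-max scaling stands).
#'
#' @param scored data frame from [r_score()].
#' @param k number of targets to return.
#' @param status optional value matched against a `status` column.
#' @return the top-`k` rows, reordered.
#' @export
rank_targets <- function(scored, k, status = NULL) {
  stopifnot("r" %in% names(scored))
  if (!is.null(status)) {
    stopifnot("status" %in% names(scored))
    scored <- scored[scored$status == status, , drop = FALSE]
  }
  key <- if ("accession" %in% names(scored)) scored$accession else scored[[1]]
  ord <- order(scored$r, -scored$betweenness, key)
  scored <- scored[ord, , drop = FALSE]
  if (k > nrow(scored)) {
    warning("k = ", k, " exceeds cohort size ", nrow(scored),
            "; returning full cohort")
    k <- nrow(scored)
  }
  head(scored, k)
}

#' Bundled key-target topology table
#'
#' Loads the packaged table of 48 candidate targets (Swiss-Prot accession,
#' gene symbol, validated/predicted status) with their average shortest path
#' length and betweenness centrality in the 432-protein interaction network,
#' as printed in the source study. The printed R column is included as
#' `r_printed` for comparison; a handful of printed R values are not
#' consistent with the printed rounded inputs (see the package vignette).
#'
#' @return data frame with columns `accession`, `gene`, `status`,
#'   `avg_shortest_path`, `betweenness`, `r_printed`.
#' @export
load_target_table <- function() {
  path <- system.file("extdata", "cki_targets_table.csv", package = "netmet",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
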