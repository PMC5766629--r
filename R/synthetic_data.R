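# Seeded generators emulating the statistical structure of the two input
# kinds the pipeline consumes: PPI graphs with planted high-centrality
# targets, and two-class 1H-NMR spectra with known discriminating
# metabolites. Both are pure functions of their arguments (seed included).

#' Simulate a PPI network with planted hub targets
#'
#' Generates a background protein interaction graph (preferential-attachment
#' or uniform random) and attaches each planted target to a prescribed
#' number of distinct background proteins. Higher planted degree yields
#' higher betweenness and shorter average paths, so the designed ordering of
#' hubs is their degree ordering — the ground truth returned for
#' prioritization tests.
#'
#' @param n_background number of background proteins.
#' @param planted_hubs named integer vector: target ID -> desired degree
#'   (each must be < `n_background`).
#' @param attachment `"preferential"` (Barabasi-Albert background) or
#'   `"uniform"` (Erdos-Renyi background).
#' @param edges_per_node background edge density: edges added per node under
#'   preferential attachment, or mean edges per node under uniform (default 2).
#' @param seed integer seed; the same seed reproduces the same graph.
#' @return list with `network` (a `netmet_network`; hubs role-tagged
#'   `target`, background `protein`) and `truth` (hub IDs ordered by
#'   designed centrality, most central first).
#' @export
gen_ppi <- function(n_background, planted_hubs,
                    attachment = c("preferential", "uniform"), seed = 1,
                    edges_per_node = 2) {
  attachment <- match.arg(attachment)
  if (is.null(names(planted_hubs)) || any(!nzchar(names(planted_hubs)))) {
    stop("planted_hubs must be a named vector (target ID -> degree)")
  }
  if (any(planted_hubs >= n_background) || any(planted_hubs < 1)) {
    stop("planted hub degrees must lie in [1, n_background)")
  }
  bg <- sprintf("P%04d", seq_len(n_background))
  withr::with_seed(seed, {
    g <- switch(attachment,
      preferential = igraph::sample_pa(n_background, m = edges_per_node,
                                       directed = FALSE),
      uniform = igraph::sample_gnm(n_background,
                                   m = edges_per_node * n_background))
    base_edges <- igraph::as_edgelist(g, names = FALSE)
    base_edges <- cbind(bg[base_edges[, 1]], bg[base_edges[, 2]])
    hub_edges <- do.call(rbind, lapply(names(planted_hubs), function(h) {
      cbind(h, sample(bg, planted_hubs[[h]]))
    }))
  })
  role <- c(setNames(rep("target", length(planted_hubs)), names(planted_hubs)),
            setNames(rep("protein", n_background), bg))
  net <- network_new(rbind(base_edges, hub_edges),
                     nodes = c(names(planted_hubs), bg), node_role = role)
  truth <- names(sort(planted_hubs, decreasing = TRUE))
  list(network = net, truth = truth)
}

#' Unit-height Lorentzian line shape
#'
#' `gamma^2 / ((x - center)^2 + gamma^2)`: height 1 at the center,
#' half-width-at-half-maximum `gamma`, the natural line shape of solution
#' NMR resonances. Its integral over `[a, b]` is
#' `gamma * (atan((b - center)/gamma) - atan((a - center)/gamma))`.
#'
#' @param x evaluation points (ppm).
#' @param center peak position (ppm).
#' @param gamma half width at half maximum (ppm).
#' @return numeric vector of intensities.
#' @export
lorentzian <- function(x, center, gamma) {
  gamma^2 / ((x - center)^2 + gamma^2)
}

#' Default two-class metabolite panel
#'
#' A cell-extract-like panel of 16 metabolites at literature 1H chemical
#' shifts, with treated/control concentration ratios following the
#' magnitude-and-direction pattern reported for hepatoma cells treated with
#' the Kushen alkaloid preparation (e.g. leucine up 4.0-fold, valine up
#' 5.4-fold, glutamate down 3.0-fold). Each entry is a list with `name`,
#' `shifts` (ppm), `weights` (relative multiplet intensities), `base`
#' (control-group concentration, arbitrary units), and `ratio`
#' (treated/control).
#'
#' @return list of metabolite specs consumable by [gen_spectra()].
#' @export
default_metabolite_panel <- function() {
  m <- function(name, shifts, weights, base, ratio) {
    list(name = name, shifts = shifts, weights = weights,
         base = base, ratio = ratio)
  }
  list(
    m("leucine",        c(0.96, 1.71), c(1, 0.5),      1.0, 4.00),
    m("valine",         c(0.99, 1.04), c(1, 1),        1.0, 5.39),
    m("acetate",        1.92,          1,              1.0, 4.81),
    m("glutamate",      c(2.08, 2.35), c(1, 0.8),      1.5, 1 / 2.98),
    m("glutamine",      c(2.14, 2.45), c(1, 0.8),      1.5, 1.52),
    m("glutathione",    c(2.17, 2.55, 2.95), c(0.7, 1, 0.8), 1.0, 1 / 4.10),
    m("creatine",       c(3.04, 3.93), c(1, 0.7),      1.0, 1 / 2.61),
    m("glycerophosphocholine", 3.23, 1,               1.0, 1 / 2.57),
    m("glycine",        3.56,          1,              1.0, 1 / 2.91),
    m("dihydroxyacetone", 4.42,        1,              0.8, 1 / 2.01),
    m("glycerol",       c(3.65, 3.78), c(1, 0.8),      1.0, 2.31),
    m("AMP",            c(8.26, 8.60), c(1, 1),        0.8, 1 / 1.52),
    m("beta-glucose",   c(3.25, 3.40), c(1, 1),        2.0, 11.05),
    m("tyrosine",       c(6.90, 7.19), c(1, 1),        0.8, 3.69),
    m("phenylalanine",  c(7.33, 7.42), c(1, 1.5),      0.8, 3.34),
    m("hypoxanthine",   c(8.19, 8.21), c(1, 1),        0.8, 1 / 3.18)
  )
}

#' Simulate two-class 1H-NMR spectra
#'
#' Evaluates each metabolite's resonances as unit-height Lorentzians on a
#' 0.001-ppm grid spanning [0.50, 9.00), scales them by the group
#' concentration (control: `base`; treated: `base * ratio`), sums across
#' metabolites, adds i.i.d. Gaussian noise and floors at zero. Ground truth
#' is the set of metabolites whose ratio differs from 1.
#'
#' @param n_per_group samples per class (default 6, a typical cell-extract
#'   NMR cohort size).
#' @param metabolites list of metabolite specs (see
#'   [default_metabolite_panel()]); names must be unique; all shifts must
#'   lie in [0.50, 9.00).
#' @param peak_width Lorentzian half width at half maximum in ppm
#'   (default 0.002).
#' @param noise_sd additive Gaussian noise SD, on the unit-height intensity
#'   scale (default 0.02, i.e. 2% of a unit peak).
#' @param seed integer seed; same seed reproduces the same matrix.
#' @param grid_step spectral grid spacing in ppm (default 0.001).
#' @return list with `spectra` (a `netmet_spectra`, groups "control" /
#'   "treated") and `truth` (character vector of differential metabolite
#'   names).
#' @export
gen_spectra <- function(n_per_group = 6,
                        metabolites = default_metabolite_panel(),
                        peak_width = 0.002, noise_sd = 0.02, seed = 1,
                        grid_step = 0.001) {
  nms <- vapply(metabolites, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    stop("duplicate metabolite name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  for (met in metabolites) {
    if (any(met$shifts < 0.50 | met$shifts >= 9.00)) {
      stop("metabolite '", met$name, "' has shifts outside [0.50, 9.00)")
    }
    if (any(met$ratio <= 0)) stop("ratios must be positive")
  }
  ppm <- seq(0.50, 9.00 - grid_step, by = grid_step)
  shape <- vapply(metabolites, function(met) {
    v <- numeric(length(ppm))
    for (k in seq_along(met$shifts)) {
      v <- v + met$weights[k] * lorentzian(ppm, met$shifts[k], peak_width)
    }
    v
  }, numeric(length(ppm)))                       # grid x metabolite
  base <- vapply(metabolites, `[[`, numeric(1), "base")
  ratio <- vapply(metabolites, `[[`, numeric(1), "ratio")
  mean_control <- as.numeric(shape %*% base)
  mean_treated <- as.numeric(shape %*% (base * ratio))
  n <- 2L * n_per_group
  groups <- rep(c("control", "treated"), each = n_per_group)
  mu <- rbind(matrix(mean_control, n_per_group, length(ppm), byrow = TRUE),
              matrix(mean_treated, n_per_group, length(ppm), byrow = TRUE))
  withr::with_seed(seed, {
    noise <- if (noise_sd > 0) {
      matrix(rnorm(n * length(ppm), sd = noise_sd), n, length(ppm))
    } else 0
  })
  intens <- pmax(mu + noise, 0)
  rownames(intens) <- paste0(groups, "_", sequence(c(n_per_group, n_per_group)))
  list(
    spectra = spectrum_set(rev(ppm),
                           intens[, length(ppm):1, drop = FALSE], groups),
    truth = nms[ratio != 1]
  )
}

#' Bin assignments for a metabolite panel
#'
#' Maps each metabolite of a panel to the ppm positions of its resonances,
#' the assignment table [call_differential()] consumes.
#'
#' @param metabolites list of metabolite specs.
#' @return named list: metabolite -> numeric ppm vector.
#' @export
panel_assignments <- function(metabolites = default_metabolite_panel()) {
  setNames(lapply(metabolites, `[[`, "shifts"),
           vapply(metabolites, `[[`, character(1), "name"))
}
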