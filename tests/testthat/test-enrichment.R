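make_gmt <- function(lines) withr::local_tempfile(lines = lines,
                                                  .local_envir = parent.frame())

test_that("GMT parsing: universe union, in-line duplicates, malformed lines", {
  f <- make_gmt(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg3\tg4\tg5"))
  coll <- read_gmt(f)
  expect_equal(length(coll$universe), 5L)
  f2 <- make_gmt("setA\tdesc\tg1\tg1\tg2")
  expect_identical(sort(read_gmt(f2)$sets$setA), c("g1", "g2"))
  f3 <- make_gmt(c("setA\tdesc\tg1", "broken_line"))
  expect_error(read_gmt(f3), "line 2")
})

test_that("GMT write -> read round-trips random collections", {
  withr::with_seed(11, {
    genes <- sprintf("G%03d", 1:60)
    sets <- lapply(setNames(1:6, paste0("S", 1:6)),
                   function(i) sort(sample(genes, sample(5:15, 1))))
  })
  coll <- list(sets = sets,
               descriptions = setNames(paste("d", 1:6), names(sets)),
               universe = sort(unique(unlist(sets))))
  f <- withr::local_tempfile()
  write_gmt(coll, f)
  back <- read_gmt(f)
  expect_identical(back$sets, coll$sets)
  expect_identical(back$universe, coll$universe)
})

test_that("hypergeometric p matches closed forms", {
  # universe 10, set 5, query 5, overlap 5 -> 1/C(10,5)
  uni <- letters[1:10]
  coll <- list(sets = list(s = letters[1:5]), universe = uni)
  res <- hypergeom_enrich(letters[1:5], coll, p_cutoff = 1)
  expect_equal(res$p, 1 / choose(10, 5), tolerance = 1e-12)
  # set = universe: every query overlaps fully, p = 1
  coll2 <- list(sets = list(all = uni), universe = uni)
  expect_equal(hypergeom_enrich(letters[1:3], coll2, p_cutoff = 1)$p, 1)
  # overlap 0: P[X >= 0] is certain
  coll3 <- list(sets = list(s = letters[1:4]), universe = uni)
  res3 <- hypergeom_enrich("j", coll3, p_cutoff = 1)
  expect_equal(res3$k, 0L)
  expect_equal(res3$p, 1)
  # ...and a singleton query overlapping is exactly the set fraction
  res4 <- hypergeom_enrich("a", coll3, p_cutoff = 1)
  expect_equal(res4$p, 4 / 10, tolerance = 1e-12)
})

test_that("hypergeometric p equals exhaustive draw enumeration on small universes", {
  cases <- list(c(N = 10, K = 4, n = 5), c(N = 12, K = 6, n = 4),
                c(N = 15, K = 5, n = 7), c(N = 9, K = 3, n = 3),
                c(N = 15, K = 10, n = 6))
  for (cs in cases) {
    uni <- sprintf("g%02d", seq_len(cs["N"]))
    coll <- list(sets = list(s = uni[seq_len(cs["K"])]), universe = uni)
    withr::with_seed(sum(cs), {
      query <- sample(uni, cs["n"])
    })
    k <- sum(query %in% coll$sets$s)
    res <- hypergeom_enrich(query, coll, p_cutoff = 1)
    expect_equal(res$p, oracle_hyper_p(cs["N"], cs["K"], cs["n"], k),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("p-values are invariant under gene relabeling", {
  uni <- sprintf("g%02d", 1:20)
  coll <- list(sets = list(s1 = uni[1:6], s2 = uni[5:12]), universe = uni)
  q <- uni[c(1:4, 9, 15)]
  withr::with_seed(4, perm <- sample(20))
  relab <- setNames(sprintf("h%02d", perm), uni)
  coll2 <- list(sets = lapply(coll$sets, function(s) unname(relab[s])),
                universe = sort(unname(relab)))
  r1 <- hypergeom_enrich(q, coll, p_cutoff = 1)
  r2 <- hypergeom_enrich(unname(relab[q]), coll2, p_cutoff = 1)
  expect_equal(r1$p[order(r1$pathway)], r2$p[order(r2$pathway)])
})

test_that("BH adjustment matches the step-up definition and is idempotent", {
  expect_equal(bh_fdr(c(0.001, 0.01, 0.03)), c(0.003, 0.015, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  for (i in 1:10) {
    withr::with_seed(500 + i, p <- runif(sample(3:40, 1)))
    adj <- bh_fdr(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))  # monotone in p-rank
  }
  expect_error(bh_fdr(c(0.1, 0)), "0, 1")
  expect_error(bh_fdr(c(0.1, 1.2)), "0, 1")
})

test_that("planted enriched set attains minimum p in >= 95% of replicates", {
  hits <- logical(100)
  withr::with_seed(99, {
    for (r in 1:100) {
      uni <- sprintf("g%03d", 1:200)
      sets <- c(list(planted = sample(uni, 25)),
                setNames(lapply(1:9, function(i) sample(uni, 25)),
                         paste0("s", 1:9)))
      coll <- list(sets = sets, universe = uni)
      # query drawn 80% from the planted set
      q <- unique(c(sample(sets$planted, 16), sample(uni, 4)))
      res <- hypergeom_enrich(q, coll, p_cutoff = 1)
      hits[r] <- res$pathway[1] == "planted"
    }
  })
  expect_gte(mean(hits), 0.95)
})

test_that("pathway impact is the matched share of betweenness, in [0, 1]", {
  p3 <- network_new(rbind(c("A", "B"), c("B", "C")))
  expect_equal(pathway_impact(p3, character(0)), 0)
  expect_equal(pathway_impact(p3, "B"), 1)          # leaves carry 0 centrality
  expect_equal(pathway_impact(p3, c("A", "B", "C")), 1)
  expect_error(pathway_impact(p3, "Z"), "absent")
  # star: any leaf set has impact 0, the center alone has impact 1
  star <- network_new(cbind("c", paste0("l", 1:4)))
  expect_equal(pathway_impact(star, c("l1", "l2")), 0)
  expect_equal(pathway_impact(star, "c"), 1)
})
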