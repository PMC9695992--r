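# DIHCP extraction, hub-star module construction, size filter and pooling.

diff_row <- function(a, b, state) {
  data.frame(protein_a = pmin(a, b), protein_b = pmax(a, b),
             count_T = 1L, count_N = 0L, f_T = 1, f_N = 0, q = 1,
             state = state, stringsAsFactors = FALSE)
}

test_that("DIHCPs are the proteins incident to differential edges", {
  d <- rbind(diff_row("A", "B", "ACTIVATED"),
             diff_row("C", "D", "SUPPRESSED"),
             diff_row("A", "C", "NONSIGNIFICANT"))
  dp <- extract_dihcps(d)
  expect_equal(dp$all, c("A", "B", "C", "D"))
  expect_equal(dp$activated, c("A", "B"))
  expect_equal(dp$suppressed, c("C", "D"))

  expect_length(extract_dihcps(diff_row("A", "B", "NONSIGNIFICANT"))$all, 0L)

  # set-union oracle on a random instance
  set.seed(42)
  genes <- sprintf("x%02d", 1:30)
  d <- do.call(rbind, lapply(1:60, function(i) {
    e <- sample(genes, 2)
    diff_row(e[1], e[2], sample(c("ACTIVATED", "SUPPRESSED",
                                  "NONSIGNIFICANT"), 1))
  }))
  keep <- d$state != "NONSIGNIFICANT"
  oracle <- sort(unique(c(d$protein_a[keep], d$protein_b[keep])))
  expect_equal(extract_dihcps(d)$all, oracle)
})

test_that("module size filter counts the hub plus its partners", {
  partners9 <- sprintf("P%02d", 1:9)
  d <- diff_row("HUB", partners9, "ACTIVATED")
  mods <- build_modules(d, min_size = 10)
  expect_length(mods, 1L)                      # 1 hub + 9 partners = 10
  expect_equal(length(mods[[1]]$members), 10L)

  d3 <- diff_row("HUB", sprintf("P%02d", 1:3), "ACTIVATED")
  expect_length(build_modules(d3, min_size = 10), 0L)
})

test_that("a star of activated edges yields one uniform module", {
  partners <- sprintf("Q%02d", 1:12)
  d <- diff_row("HUB", partners, "ACTIVATED")
  mods <- build_modules(d, min_size = 10)
  expect_length(mods, 1L)
  m <- mods[[1]]
  expect_equal(m$name, "mHUB")
  expect_equal(length(m$members), 13L)
  expect_equal(m$state, "ALL_ACTIVATED")
})

test_that("module state reflects its edge composition", {
  m_mixed <- mk_module("H", sprintf("P%d", 1:5),
                       c(rep("ACTIVATED", 4), "SUPPRESSED"))
  expect_equal(m_mixed$state, "MIXED")
  m_sup <- mk_module("H", sprintf("P%d", 1:2), "SUPPRESSED")
  expect_equal(module_state(m_sup), "ALL_SUPPRESSED")
})

test_that("pooling merges identical members, keeps disjoint modules apart", {
  shared <- sprintf("S%02d", 1:10)
  a <- mk_module("AAA", shared, "ACTIVATED")
  b <- mk_module("BBB", shared, "ACTIVATED")
  pooled <- pool_modules(list(a, b))
  expect_length(pooled, 1L)
  expect_setequal(pooled[[1]]$hubs, c("AAA", "BBB"))

  c1 <- mk_module("CCC", sprintf("C%02d", 1:6), "ACTIVATED")
  d1 <- mk_module("DDD", sprintf("D%02d", 1:6), "ACTIVATED")
  expect_length(pool_modules(list(c1, d1)), 2L)
})

test_that("proteasome and 14-3-3 pooled modules get their family names", {
  shared <- sprintf("S%02d", 1:8)
  a <- mk_module("PSMB3", c(shared, "X1", "X2"), "ACTIVATED")
  b <- mk_module("PSMB7", c(shared, "Y1"), "ACTIVATED")
  pooled <- pool_modules(list(a, b))     # overlap 8/min(11,10) >= 0.7
  expect_length(pooled, 1L)
  expect_equal(pooled[[1]]$name, "mPSMcomp")

  y1 <- mk_module("YWHAB", shared, "ACTIVATED")
  y2 <- mk_module("SFN", shared, "ACTIVATED")
  expect_equal(pool_modules(list(y1, y2))[[1]]$name, "mYWHAcomp")

  g1 <- mk_module("GNB1", shared, "ACTIVATED")
  g2 <- mk_module("JUN", shared, "ACTIVATED")
  expect_equal(pool_modules(list(g1, g2))[[1]]$name, "mGNB1+JUN")
})

test_that("pooling threshold validation and overlap-coefficient semantics", {
  expect_error(pool_modules(list(), overlap_threshold = 0), "overlap_threshold")
  expect_error(pool_modules(list(), overlap_threshold = 1.2), "overlap_threshold")
  # overlap = |A n B| / min sizes: 5 shared, sizes 7 and 11 -> 5/7 >= 0.7
  sh <- sprintf("S%d", 1:5)
  a <- mk_module("AAA", c(sh, "A1"), "ACTIVATED")        # 7 members
  b <- mk_module("BBB", c(sh, sprintf("B%d", 1:5)), "ACTIVATED")  # 11 members
  expect_length(pool_modules(list(a, b), 0.70), 1L)
  expect_length(pool_modules(list(a, b), 0.72), 2L)
})

test_that("pooling is a fixed point, order-invariant and loses no protein", {
  for (seed in 1:10) {
    mods <- random_module_collection(seed)
    pooled <- pool_modules(mods)
    expect_identical(module_signature(pool_modules(pooled)),
                     module_signature(pooled))
    set.seed(seed + 1000)
    shuffled <- mods[sample(length(mods))]
    expect_identical(module_signature(pool_modules(shuffled)),
                     module_signature(pooled))
    before <- sort(unique(unlist(lapply(mods, `[[`, "members"))))
    after <- sort(unique(unlist(lapply(pooled, `[[`, "members"))))
    expect_identical(before, after)
  }
})

test_that("module exports write TSV, SIF and GraphML", {
  m <- mk_module("HUB", sprintf("P%02d", 1:10), "ACTIVATED")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  sif <- withr::local_tempfile(fileext = ".sif")
  gml <- withr::local_tempfile(fileext = ".graphml")
  df <- modules_table(list(m), tsv)
  expect_true(file.exists(tsv))
  expect_equal(read.delim(tsv)$n_members, 11L)
  write_modules_graph(list(m), sif, gml)
  expect_equal(length(readLines(sif)), 10L)
  expect_true(any(grepl("graphml", readLines(gml, n = 5))))
})
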