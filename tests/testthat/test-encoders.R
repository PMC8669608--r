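test_that("GAAC reproduces known group frequencies and normalizes", {
  v <- gaac_encode("EAHGAFLMDKPSMFNERV")
  expect_equal(unname(v * 18), c(7, 2, 3, 3, 3))
  expect_equal(sum(v), 1)

  expect_equal(unname(gaac_encode("GGGG")), c(1, 0, 0, 0, 0))
  expect_error(gaac_encode(""), "empty")

  # composition is order-free and always sums to 1
  set.seed(7)
  for (i in 1:20) {
    s <- random_seq(sample(10:50, 1))
    perm <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
    expect_identical(gaac_encode(s), gaac_encode(perm))
    expect_equal(sum(gaac_encode(s)), 1)
  }
})

test_that("GAAC groups partition the alphabet", {
  g <- gaac_groups()
  expect_length(unlist(g), 20)
  expect_setequal(unlist(g), AA20)
})

test_that("physicochemical table is 20 x 3 and standardized", {
  tab <- load_physchem()
  expect_equal(dim(tab), c(20L, 3L))
  expect_equal(rownames(tab), AA20)
  expect_equal(unname(colMeans(tab)), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(colMeans(tab^2)), rep(1, 3), tolerance = 1e-12)
})

test_that("cross-covariance has 12 components and vanishes on homopolymers", {
  v <- cc_encode("AAAAAAA")
  expect_length(v, 12)
  expect_equal(unname(v), rep(0, 12))
  expect_error(cc_encode("AC", lg = 2), "too short")
})

test_that("cross-covariance matches the term-by-term oracle", {
  tab <- load_physchem()
  set.seed(11)
  for (i in 1:25) {
    s <- random_seq(10)
    expect_equal(cc_encode(s, tab), brute_cc(s, tab), tolerance = 1e-12)
    expect_equal(cc_encode(s, tab, normalize = TRUE),
                 brute_cc(s, tab, normalize = TRUE), tolerance = 1e-12)
  }
})

test_that("cross-covariance is invariant to shifting a property scale", {
  tab <- load_physchem(standardize = FALSE)
  shifted <- tab
  shifted[, "mass"] <- shifted[, "mass"] + 100
  set.seed(3)
  for (i in 1:10) {
    s <- random_seq(30)
    expect_equal(cc_encode(s, tab), cc_encode(s, shifted),
                 tolerance = 1e-9)
  }
})

test_that("monoDiKGap enumeration has the right size and order", {
  e2 <- enumerate_monodikgap(2)
  expect_length(e2, 16000)
  expect_length(enumerate_monodikgap(1), 8000)
  expect_equal(e2[1], "A_AA")
  expect_equal(e2[8001], "A__AA")
  expect_false(anyDuplicated(e2) > 0)
  expect_error(enumerate_monodikgap(0), "kgap")

  for (k in 1:3)
    expect_length(monodikgap_encode("ACDEFGHIKL", k),
                  length(enumerate_monodikgap(k)))
})

test_that("monoDiKGap counts windows as documented", {
  v <- monodikgap_encode("AAAA", 2)
  expect_equal(unname(v["A_AA"]), 1)           # the single gap-1 window
  expect_equal(sum(v[1:8000]), 1)
  expect_equal(sum(v[8001:16000]), 0)          # no gap-2 window at L = 4

  expect_equal(monodikgap_encode("ACACA", 1), brute_monodikgap("ACACA", 1))

  set.seed(19)
  for (i in 1:10) {
    s <- random_seq(sample(10:50, 1))
    expect_equal(monodikgap_encode(s, 2), brute_monodikgap(s, 2),
                 tolerance = 1e-12)
    v <- monodikgap_encode(s, 2)
    expect_equal(sum(v[1:8000]), 1)
    expect_equal(sum(v[8001:16000]), 1)
  }
})

test_that("hybrid encoding concatenates blocks in fixed order", {
  d <- protein_dataset(c("a", "b"),
                       c("EAHGAFLMDKPSMFNERV", "ACDEFGHIKLMNPQRSTVWY"),
                       c(1, -1))
  m <- hybrid_encode(d, parts = c("cc", "gaac"))
  expect_equal(ncol(m$values), 17)
  expect_equal(rownames(m$values), d$id)
  expect_equal(m$labels, c(1, -1))

  # gaac-only equals row-wise gaac_encode
  mg <- hybrid_encode(d, parts = "gaac")
  expect_equal(unname(mg$values[1, ]), unname(gaac_encode(d$sequence[1])))

  # parts order in the call does not matter; block order is fixed
  m2 <- hybrid_encode(d, parts = c("gaac", "cc"))
  expect_identical(colnames(m2$values), colnames(m$values))

  expect_error(hybrid_encode(d, parts = character(0)))
  expect_error(hybrid_encode(d, parts = "cc", monodikgap_subset = "A_AA"),
               NA)  # subset ignored when monodikgap absent is not an error
})

test_that("a restricted monoDiKGap block yields the reduced hybrid width", {
  d <- protein_dataset(c("a", "b"),
                       c(random_seq(40), random_seq(40)), c(1, -1))
  subset466 <- enumerate_monodikgap(2)[101:566]
  m <- hybrid_encode(d, monodikgap_subset = subset466)
  expect_equal(ncol(m$values), 466 + 12 + 5)
  expect_error(hybrid_encode(d, monodikgap_subset = "Z__ZZZ"), "unknown")
})
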