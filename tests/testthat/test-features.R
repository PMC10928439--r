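test_that("localization features follow the four set comparisons", {
  expect_equal(unname(localization_features("nucleus", "nucleus")),
               c(1, 1, 1, 1))
  expect_equal(unname(localization_features("nucleus", "membrane")),
               c(0, 0, 0, 0))
  expect_equal(unname(localization_features(c("nucleus", "cytoplasm"),
                                            "nucleus")),
               c(1, 0, 0.5, 1))
  # empty-set conventions: equal and mutually inclusive, Jaccard 0
  expect_equal(unname(localization_features(character(), character())),
               c(0, 1, 0, 1))
  # one-sided empty: included but not equal
  expect_equal(unname(localization_features(character(), "nucleus")),
               c(0, 0, 0, 1))
})

test_that("domain features count overlaps and known domain interactions", {
  ddi <- domain_interaction_set(data.frame(d1 = "d1", d2 = "d3"))
  expect_equal(unname(domain_features(c("d1", "d2"), c("d2", "d3"), ddi)),
               c(1, 1, 3, 1 / 3, 1 / 3))
  expect_equal(unname(domain_features(character(), character(), ddi)),
               c(0, 0, 0, 0, 0))
  expect_equal(unname(domain_features("d1", "d1", NULL)),
               c(1, 0, 1, 1, 0))
  # symmetric ddi membership: order of the pair file does not matter
  ddi_rev <- domain_interaction_set(data.frame(d1 = "d3", d2 = "d1"))
  expect_equal(domain_features(c("d1", "d2"), c("d2", "d3"), ddi_rev),
               domain_features(c("d1", "d2"), c("d2", "d3"), ddi))
})

test_that("chain-length feature is the absolute difference, symmetric", {
  expect_equal(chain_length_feature(350, 350), 0)
  expect_equal(chain_length_feature(50, 2000), 1950)
  expect_equal(chain_length_feature(120, 75), chain_length_feature(75, 120))
  expect_true(is.na(chain_length_feature(NA, 100)))
})

test_that("GO similarity uses the Jaccard fallback and masks provider failures", {
  expect_equal(go_similarity(c("g1", "g2"), c("g1", "g2")), 1)
  expect_equal(go_similarity("g1", "g2"), 0)
  expect_equal(go_similarity(c("g1", "g2"), "g1"), 0.5)
  expect_equal(go_similarity(character(), character()), 0)
  # custom provider is honored, failure is masked with a warning
  expect_equal(go_similarity("g1", "g2", provider = function(a, b) 0.42), 0.42)
  expect_warning(
    v <- go_similarity("g1", "g2", provider = function(a, b) stop("boom")),
    "masked")
  expect_true(is.na(v))
  expect_error(go_similarity("g1", "g2", provider = function(a, b) 2),
               "outside")
})

test_that("all pair features are symmetric in the two proteins", {
  set.seed(3)
  terms <- sprintf("t%d", 1:8)
  ddi <- domain_interaction_set(data.frame(d1 = c("t1", "t2"),
                                           d2 = c("t5", "t6")))
  for (i in 1:25) {
    si <- sample(terms, sample(0:4, 1L)); sj <- sample(terms, sample(0:4, 1L))
    expect_equal(localization_features(si, sj), localization_features(sj, si))
    expect_equal(domain_features(si, sj, ddi), domain_features(sj, si, ddi))
    expect_equal(go_similarity(si, sj), go_similarity(sj, si))
  }
})

test_that("inclusion with both sets non-empty pins Jaccard to the size ratio", {
  set.seed(4)
  terms <- sprintf("t%d", 1:10)
  for (i in 1:50) {
    si <- sample(terms, sample(1:5, 1L))
    sj <- sample(terms, sample(1:5, 1L))
    f <- localization_features(si, sj)
    if (f[["inclusion"]] == 1) {
      nu <- length(unique(si)); nv <- length(unique(sj))
      expect_equal(f[["jaccard"]], min(nu, nv) / max(nu, nv))
    }
  }
})

test_that("min-max scaling maps to [0,1], clamps, zeroes constants, idempotent", {
  train <- data.frame(x = c(0, 5, 10), y = c(3, 3, 3))
  scaled <- scale_features(train)
  expect_equal(scaled$x, c(0, 0.5, 1))
  expect_equal(scaled$y, c(0, 0, 0))
  # clamp out-of-range test values under the training scaler
  scaler <- attr(scaled, "scaler")
  test <- scale_features(data.frame(x = c(-2, 12), y = c(9, 9)), scaler)
  expect_equal(test$x, c(0, 1))
  # masked missing values impute to 0 and are flagged
  miss <- scale_features(data.frame(x = c(NA, 5), y = c(3, NA)), scaler)
  expect_equal(miss$x, c(0, 0.5))
  expect_equal(unname(attr(miss, "missing_mask")[, "x"]), c(TRUE, FALSE))
  # idempotent: transforming already-scaled data with a fresh fit is a no-op
  twice <- scale_features(scaled[, c("x", "y")])
  expect_equal(twice$x, scaled$x)
  expect_equal(twice$y, scaled$y)
})

test_that("edge feature assembly joins annotations, masks gaps, reads tables", {
  ann <- protein_annotations(
    localization = list(a = c("nucleus", "cytoplasm"), b = "nucleus",
                        c = "membrane"),
    domains = list(a = c("d1", "d2"), b = c("d2", "d3"), c = character()),
    chain_length = c(a = 350, b = 400, c = 120),
    go = list(a = c("g1", "g2"), b = "g1", c = "g9"))
  ddi <- domain_interaction_set(data.frame(d1 = "d1", d2 = "d3"))
  pairs <- data.frame(u = c("a", "a", "a"), v = c("b", "c", "zz"))
  fe <- compute_edge_features(pairs, ann, ddi = ddi)
  expect_equal(fe$overlap_sl[1], 1)
  expect_equal(fe$jaccard[1], 0.5)
  expect_equal(fe$interaction[1], 1)
  expect_equal(fe$chain_length_diff[1], 50)
  expect_equal(fe$go_similarity[1], 0.5)
  # unannotated partner masks every block
  expect_true(all(is.na(fe[3, -(1:2)])))
  # annotation table round-trip
  f <- withr::local_tempfile()
  writeLines(c("a\tnucleus;cytoplasm", "b\tnucleus", "c\t"), f)
  loc <- read_annotation_table(f, "terms")
  expect_equal(loc$a, c("nucleus", "cytoplasm"))
  expect_equal(loc$c, character())
  writeLines(c("a\t350", "b\t400"), f)
  expect_equal(read_annotation_table(f, "numeric"), c(a = 350, b = 400))
  # precomputed extra block joins by pair key
  extra <- data.frame(u = "b", v = "a", pssm_dist = 0.25)
  fe2 <- compute_edge_features(pairs, ann, extra_block = extra)
  expect_equal(fe2$pssm_dist, c(0.25, NA, NA))
})
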