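test_that("density, modularity and cohesion score match hand evaluation", {
  # isolated weight-1 triangle: the maximal case
  tri <- weighted_pin(data.frame(u = c("a", "b", "a"), v = c("b", "c", "c"),
                                 weight = 1))
  s <- complex_score(tri, c("a", "b", "c"))
  expect_equal(unname(s[c("D", "M", "F")]), c(1, 1, 1.5))
  # worked 4-node instance
  s2 <- complex_score(worked_pin(), c("a", "b", "c"))
  expect_equal(s2[["D"]], 2.6 / 3)
  expect_equal(s2[["M"]], 2.6 / 2.9)
  expect_equal(s2[["F"]], 1 / (3 / 2.6 + 2.9 / 2.6) + (2.6 / 3 + 2.6 / 2.9) / 2)
  expect_equal(s2[["F"]], 1.3222872, tolerance = 1e-6)
  # singletons score zero
  expect_equal(complex_score(worked_pin(), "a")[["F"]], 0)
  # internal-weight-free pairs score zero
  expect_equal(complex_score(worked_pin(), c("a", "d"))[["F"]], 0)
  expect_error(complex_score(worked_pin(), c("a", "zz")), "not in network")
})

test_that("inflate follows the four addition criteria on the worked instance", {
  pin <- worked_pin()
  # first addition: b (F 0.8731) beats c (F 0.7430)
  f_ab <- complex_score(pin, c("a", "b"))[["F"]]
  f_ac <- complex_score(pin, c("a", "c"))[["F"]]
  expect_gt(f_ab, f_ac)
  res <- inflate(pin, "a")
  expect_equal(res$members, c("a", "b", "c"))
  expect_equal(res$score[["F"]], 1.3222872, tolerance = 1e-6)
  # d is blocked by the c-edge weight gate (0.3 <= 0.5)
  expect_false("d" %in% res$members)
  # a seed with no strong neighbor stays a singleton
  weak <- weighted_pin(data.frame(u = "x", v = "y", weight = 0.4))
  expect_equal(inflate(weak, "x")$members, "x")
  # an isolated weight-1 clique is grown completely, reaching F = 1.5
  clique <- weighted_pin(data.frame(u = c("p", "q", "p"), v = c("q", "r", "r"),
                                    weight = 1))
  grown <- inflate(clique, "p")
  expect_equal(grown$members, c("p", "q", "r"))
  expect_equal(grown$score[["F"]], 1.5)
})

test_that("inflate enforces the expectation-edges criterion", {
  # high-F pair {a, b}; node z attached by one strong edge:
  # Actually = 1 < Expectation = F * 2, so z must be rejected even though
  # it passes the weight gate
  pin <- weighted_pin(data.frame(u = c("a", "a"), v = c("b", "z"),
                                 weight = c(1, 0.6)))
  f_ab <- complex_score(pin, c("a", "b"))[["F"]]
  expect_gt(f_ab * 2, 1)  # the criterion really is binding here
  res <- inflate(pin, "a")
  expect_false("z" %in% res$members)
})

test_that("shrink removes weakly attached members only when the score improves", {
  pin <- worked_pin()
  # {a,b,c} is already optimal: every removal lowers F
  res <- shrink(pin, c("a", "b", "c"))
  expect_equal(res$members, c("a", "b", "c"))
  # a member held by a single barely-strong edge with heavy outside pull
  # is removed and F increases
  pin2 <- weighted_pin(data.frame(
    u = c("a", "b", "a", "c", "w", "w", "w"),
    v = c("b", "c", "c", "w", "x", "y", "z"),
    weight = c(0.9, 0.9, 0.9, 0.51, 0.9, 0.9, 0.9)))
  f_with <- complex_score(pin2, c("a", "b", "c", "w"))[["F"]]
  f_without <- complex_score(pin2, c("a", "b", "c"))[["F"]]
  expect_gt(f_without, f_with)
  res2 <- shrink(pin2, c("a", "b", "c", "w"))
  expect_equal(res2$members, c("a", "b", "c"))
  expect_equal(res2$score[["F"]], f_without)
  # a subgraph with no boundary nodes is untouched
  iso <- weighted_pin(data.frame(u = c("p", "q", "p"), v = c("q", "r", "r"),
                                 weight = 1))
  expect_equal(shrink(iso, c("p", "q", "r"))$members, c("p", "q", "r"))
})

test_that("inflate and shrink never decrease the cohesion score", {
  set.seed(12)
  for (i in 1:20) {
    pin <- random_pin(12, 0.3)
    if (pin_edge_count(pin) == 0L) next
    seed_node <- sample(pin$nodes, 1L)
    f0 <- complex_score(pin, seed_node)[["F"]]
    grown <- inflate(pin, seed_node)
    expect_gte(grown$score[["F"]], f0)
    trimmed <- shrink(pin, grown$members)
    expect_gte(trimmed$score[["F"]], grown$score[["F"]])
  }
})

test_that("detection recovers planted structure and scores known cases", {
  # two weight-0.7 4-cliques joined by a single weight-0.1 bridge: the
  # bridge fails the c-edge weight gate, so the cliques are recovered whole
  cl <- function(ids) {
    pr <- utils::combn(ids, 2L)
    data.frame(u = pr[1L, ], v = pr[2L, ], weight = 0.7)
  }
  pin <- weighted_pin(rbind(cl(c("a1", "a2", "a3", "a4")),
                            cl(c("b1", "b2", "b3", "b4")),
                            data.frame(u = "a1", v = "b1", weight = 0.1)))
  cs <- detect_complexes(pin)
  keys <- vapply(cs$members, paste, "", collapse = " ")
  expect_setequal(keys, c("a1 a2 a3 a4", "b1 b2 b3 b4"))
  # empty graph
  expect_equal(length(detect_complexes(weighted_pin())), 0L)
  # a single isolated weighted edge
  pair <- weighted_pin(data.frame(u = "u", v = "v", weight = 0.9))
  cs2 <- detect_complexes(pair)
  expect_equal(cs2$members, list(c("u", "v")))
  expect_equal(cs2$score, 1 / (1 / 0.9 + 1) + (0.9 + 1) / 2, tolerance = 1e-9)
  # the worked instance yields exactly {a, b, c}
  cs3 <- detect_complexes(worked_pin())
  expect_equal(cs3$members, list(c("a", "b", "c")))
  expect_equal(cs3$score, 1.3222872, tolerance = 1e-6)
})

test_that("small planted complexes (pairs) survive weak surroundings", {
  pin <- weighted_pin(data.frame(
    u = c("p", "p", "q", "x"), v = c("q", "x", "y", "y"),
    weight = c(0.9, 0.15, 0.2, 0.1)))
  cs <- detect_complexes(pin)
  expect_true(any(vapply(cs$members, identical, TRUE, c("p", "q"))))
})

test_that("duplicate removal keeps one copy of identical member sets only", {
  cs <- complex_set(list(c("a", "b", "c"), c("a", "b", "c"), c("a", "b")),
                    c(1.2, 1.2, 0.9))
  dd <- deduplicate_complexes(cs)
  expect_equal(length(dd), 2L)
  # {a,b} vs {a,b,c}: matching rate 4/6 < 1, both kept
  expect_setequal(vapply(dd$members, paste, "", collapse = " "),
                  c("a b c", "a b"))
  # idempotent
  expect_identical(deduplicate_complexes(dd), dd)
  # canonical order: descending score then lexicographic members
  expect_equal(dd$score, c(1.2, 0.9))
})

test_that("cohesion score is bounded and maximal only on isolated unit cliques", {
  set.seed(13)
  n_checked <- 0L
  for (i in 1:40) {
    pin <- random_pin(10, 0.35)
    if (pin_edge_count(pin) == 0L) next
    for (j in 1:25) {
      members <- sample(pin$nodes, sample(2:6, 1L))
      s <- complex_score(pin, members)
      expect_gte(s[["F"]], 0)
      expect_lte(s[["F"]], 1.5)
      if (s[["F"]] == 1.5) {
        expect_equal(s[["D"]], 1)
        expect_equal(s[["M"]], 1)
        expect_equal(s[["d_out"]], 0)
      }
      n_checked <- n_checked + 1L
    }
  }
  expect_gte(n_checked, 500L)
})

test_that("detection output is independent of the worker count", {
  pt <- generate_planted_pin(n_complexes = 12L, sizes = 2:6,
                             background_p = 0.02, seed = 31)
  cs1 <- detect_complexes(pt$pin, workers = 1L)
  cs4 <- detect_complexes(pt$pin, workers = 4L)
  expect_identical(cs1, cs4)
  expect_identical(cs1, detect_complexes(pt$pin, workers = 1L))
})
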