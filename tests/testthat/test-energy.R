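# Five-term coarse-grained potential: brute-force parity, analytic anchor
# points, invariances, and the budget-accounting contract.

test_that("every term matches its brute-force double-loop oracle", {
  set.seed(101)
  p <- amw_params()
  for (rep in 1:6) {
    conf <- random_conformation(sample(4:10, 1))
    co <- coordinates(conf)
    expect_equal(lj_term(co, p), bf_lj(co, p), tolerance = 1e-9)
    expect_equal(hbond_term(co, p), bf_hbond(co, p), tolerance = 1e-9)
    expect_equal(compaction_term(co, p), bf_compaction(co, p),
                 tolerance = 1e-9)
    expect_equal(burial_term(co, p), bf_burial(co, p), tolerance = 1e-9)
    expect_identical(burial_contact_counts(co, p), bf_burial_counts(co, p))
    expect_equal(water_term(co, p), bf_water(co, p), tolerance = 1e-9)
  }
})

test_that("the total is the sum of the five terms", {
  set.seed(13)
  for (rep in 1:10) {
    conf <- random_conformation(6)
    b <- amw_breakdown(conf)
    expect_equal(unname(b["total"]), sum(b[1:5]), tolerance = 1e-9)
    expect_equal(score_total(conf), unname(b["total"]), tolerance = 1e-12)
  }
})

test_that("every term is invariant under rigid transforms", {
  set.seed(29)
  for (rep in 1:5) {
    co <- coordinates(random_conformation(8))
    co2 <- rigid_transform(co, angle = stats::runif(1, 0, pi),
                           shift = stats::rnorm(3, sd = 10))
    b1 <- amw_breakdown(co)
    b2 <- amw_breakdown(co2)
    expect_equal(b1, b2, tolerance = 1e-9)
  }
})

test_that("LJ has its analytic minimum and decays at long range", {
  p <- amw_params()
  rmin <- 2 * p$lj_radius["CB"]
  eps <- p$lj_eps["CB"]
  pair_e <- function(r) evodecoy:::.lj_pair(r, rmin, eps, p$lj_cap_frac)
  expect_equal(pair_e(rmin), -eps, tolerance = 1e-12, ignore_attr = TRUE)
  expect_lt(abs(pair_e(10 * rmin)), 1e-5 * eps)
})

test_that("soft-core LJ is continuous at the cap and monotone below it", {
  p <- amw_params()
  rmin <- 2 * p$lj_radius["N"]
  eps <- p$lj_eps["N"]
  rc <- p$lj_cap_frac * rmin
  pair_e <- function(r) evodecoy:::.lj_pair(r, rmin, eps, p$lj_cap_frac)
  expect_equal(pair_e(rc - 1e-9), pair_e(rc + 1e-9), tolerance = 1e-6,
               ignore_attr = TRUE)
  rs <- seq(rc, 1e-3, length.out = 50)
  es <- vapply(rs, pair_e, numeric(1))
  expect_true(all(diff(es) > 0))   # energy rises as r decreases
  expect_true(all(is.finite(es)))
})

test_that("hydrogen bonds peak at -w_hb for an ideal collinear geometry", {
  p <- amw_params()
  # two residues far apart in sequence; place O(1)...N(5) at the ideal
  # distance with C(1)=O(1)...N(5) collinear by direct construction
  co <- coordinates(extended_conformation(strrep("A", 5)))
  dir <- co$O[1, ] - co$C[1, ]
  dir <- dir / sqrt(sum(dir^2))
  co$N[5, ] <- co$O[1, ] + p$hb_d0 * dir
  # move everything else out of range so only this pair contributes
  for (a in c("CA", "C", "O")) co[[a]][5, ] <- co$N[5, ] + c(50, 0, 0)
  co$CB[5, ] <- co$N[5, ] + c(50, 0, 0)
  for (i in 2:4) for (a in c("N", "CA", "C", "O", "CB"))
    co[[a]][i, ] <- c(500 + 10 * i, 0, 0)
  expect_equal(hbond_term(co, p), -p$hb_w, tolerance = 1e-9)
  expect_lte(hbond_term(coordinates(random_conformation(8))), 0)
})

test_that("no N...O pair within tolerance gives a zero hydrogen-bond term", {
  co <- coordinates(extended_conformation(strrep("A", 10)))
  expect_identical(hbond_term(co), 0)
})

test_that("compaction is a hinge at the target radius of gyration", {
  p <- amw_params()
  co <- coordinates(extended_conformation(strrep("A", 30)))
  expect_equal(compaction_term(co, p), bf_compaction(co, p),
               tolerance = 1e-9)
  expect_gt(compaction_term(co, p), 0)    # extended 30-mer is expanded
  # compact cluster below target -> exactly 0
  one <- coordinates(extended_conformation("A"))
  expect_identical(compaction_term(one, p), 0)
})

test_that("a dispersed chain has zero burial contacts and zero water term", {
  # straight chain with huge spacing: every pairwise CB distance > shells
  n <- 6
  seqs <- c("L", "S", "F", "K", "A", "E")
  co <- coordinates(extended_conformation("AAAAAA"))
  co$sequence <- seqs
  for (i in seq_len(n)) for (a in c("N", "CA", "C", "O", "CB"))
    co[[a]][i, ] <- co[[a]][i, ] + c(100 * i, 0, 0)
  p <- amw_params()
  expect_identical(burial_contact_counts(co, p), integer(n))
  hph <- seqs %in% p$hydrophobic
  expect_equal(burial_term(co, p),
               sum(ifelse(hph, p$w_burial * p$burial_t_hphob, 0)),
               tolerance = 1e-12)
  expect_identical(water_term(co, p), 0)
})

test_that("water pairs on the shell plateau contribute exactly w_pair", {
  p <- amw_params()
  # two residues 3 apart in sequence, side centres at mid-shell distance
  co <- coordinates(extended_conformation("AAAA"))
  mid <- (p$water_inner + p$water_outer) / 2
  for (a in c("N", "CA", "C", "O")) co[[a]][2:3, ] <- co[[a]][2:3, ] + 500
  co$CB[2, ] <- co$CB[1, ] + 600
  co$CB[3, ] <- co$CB[1, ] + 700
  co$CB[4, ] <- co$CB[1, ] + c(mid, 0, 0)
  expect_equal(water_term(co, p), unname(p$w_water["HH"]), tolerance = 1e-9)
})

test_that("burial responds to hydrophobicity classes only", {
  set.seed(61)
  conf <- random_conformation(7, sequence = c("L", "L", "S", "S", "F", "K",
                                              "A"))
  co <- coordinates(conf)
  perm <- c("K", "S", "L", "F", "S", "L", "A")  # same classes, new order
  co2 <- co
  co2$sequence <- perm
  # identical coordinates, permuted labels: totals differ only through class
  p <- amw_params()
  expect_equal(burial_term(co2, p), bf_burial(co2, p), tolerance = 1e-9)
})

test_that("the ideal helix scores below the extended chain (12-mer)", {
  helix <- conformation(strrep("A", 12),
                        cbind(rep(-57, 12), rep(-47, 12), rep(180, 12)))
  ext <- extended_conformation(strrep("A", 12))
  expect_lt(score_total(helix), score_total(ext))
  expect_lt(hbond_term(coordinates(helix)), 0)
})

test_that("scoring advances the shared budget counter; breakdown does not", {
  m <- amw_energy_model("AAAAA")
  conf <- extended_conformation("AAAAA")
  expect_identical(budget_spent(m$counter), 0L)
  invisible(score_energy(m, conf))
  expect_identical(budget_spent(m$counter), 1L)
  invisible(energy_breakdown(m, conf))
  expect_identical(budget_spent(m$counter), 1L)
  invisible(score_energy(m, conf))
  expect_identical(budget_spent(m$counter), 2L)
})
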