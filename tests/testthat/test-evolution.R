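# Search machinery: parent selection, truncation survival, greedy
# minimization, and the budget-guarded generational loop.

test_that("parent-selection weights follow the stated linear law", {
  w <- parent_weights(c(0, 5, 10))
  expect_equal(w, c(10.1, 5.1, 0.1) / 15.3, tolerance = 1e-12)
  expect_equal(parent_weights(rep(3.7, 8)), rep(1 / 8, 8))
})

test_that("empirical selection frequencies match the weighting law", {
  set.seed(55)
  energy <- c(0, 5, 10)
  p <- parent_weights(energy)
  ndraw <- 30000
  idx <- select_parent_index(energy, ndraw)
  obs <- tabulate(idx, 3)
  expect_true(all(abs(obs - ndraw * p) <= 3 * sqrt(ndraw * p * (1 - p))))
})

test_that("truncation keeps exactly the lowest-energy members (sort oracle)", {
  set.seed(65)
  n <- 6
  for (rep in 1:50) {
    np <- sample(3:30, 1)
    nc <- sample(1:30, 1)
    ps <- sample(2:np, 1)
    parents <- population("AAAAAA",
                          matrix(stats::runif(np * 3 * n), np, 3 * n),
                          round(stats::runif(np, 0, 5), 1),
                          member_id = seq_len(np))
    ca <- matrix(stats::runif(nc * 3 * n), nc, 3 * n)
    ce <- round(stats::runif(nc, 0, 5), 1)
    nxt <- truncation_select(parents, ca, ce, pop_size = ps)
    merged <- c(parents$energy, ce)
    expect_identical(sort(nxt$energy),
                     sort(merged[order(merged)[seq_len(ps)]]))
    expect_identical(nrow(nxt$angles), ps)
  }
})

test_that("truncation ties prefer parents and are deterministic", {
  n <- 6
  parents <- population("AAAAAA", matrix(1, 2, 3 * n), c(2, 2),
                        member_id = c(1L, 2L))
  nxt <- truncation_select(parents, matrix(2, 2, 3 * n), c(2, 2),
                           child_id = c(3L, 4L), pop_size = 2)
  expect_identical(nxt$member_id, c(1L, 2L))   # parents win at equal energy
  # all children worse -> parents unchanged (elitism of truncation)
  nxt2 <- truncation_select(parents, matrix(0, 2, 3 * n), c(9, 8),
                            child_id = c(3L, 4L), pop_size = 2)
  expect_identical(sort(nxt2$member_id), c(1L, 2L))
})

test_that("greedy minimization halts after n consecutive rejections on a fixed point", {
  set.seed(71)
  sys <- make_toy_system(7, entries_per_window = 1, seed = 3)
  conf <- sys$target
  lib <- sys$library   # single entry per window = target windows
  model <- toy_energy_model(sys$target)
  conf$energy <- score_energy(model, conf)
  out <- greedy_minimize(conf, lib, model)
  expect_identical(attr(out, "proposals"), 7L)   # exactly n proposals
  expect_identical(attr(out, "accepted"), 0L)
  expect_identical(out$energy, conf$energy)
  # counter: 1 initial score + n rejected proposals
  expect_identical(budget_spent(model$counter), 8L)
})

test_that("greedy minimization never increases energy and decreases monotonically", {
  set.seed(73)
  sys <- make_toy_system(10, entries_per_window = 3, seed = 8)
  model <- toy_energy_model(sys$target)
  for (rep in 1:10) {
    conf <- randomize_conformation(extended_conformation(sys$sequence),
                                   sys$library)
    conf$energy <- score_energy(model, conf)
    out <- greedy_minimize(conf, sys$library, model)
    expect_lte(out$energy, conf$energy)
  }
})

test_that("greedy minimization attains the exhaustive-enumeration optimum", {
  for (case in list(list(n = 5, k = 2, seed = 17),
                    list(n = 6, k = 3, seed = 23))) {
    sys <- make_toy_system(case$n, entries_per_window = case$k,
                           seed = case$seed)
    best_enum <- enumerate_sweep_optimum(sys$library, sys$target)
    expect_identical(best_enum, 0)     # planted target is the global optimum
    model <- toy_energy_model(sys$target)
    reached <- Inf
    set.seed(case$seed)
    for (rep in 1:10) {
      conf <- randomize_conformation(extended_conformation(sys$sequence),
                                     sys$library)
      conf$energy <- score_energy(model, conf)
      out <- greedy_minimize(conf, sys$library, model)
      reached <- min(reached, out$energy)
    }
    expect_equal(reached, best_enum, tolerance = 1e-9)
  }
})

test_that("the initial population scores once per member", {
  sys <- make_toy_system(8, entries_per_window = 2, seed = 4)
  model <- toy_energy_model(sys$target, counter = budget_counter(100))
  set.seed(3)
  pop <- initial_population(sys$sequence, sys$library, model, 5)
  expect_identical(budget_spent(model$counter), 5L)
  expect_identical(nrow(pop$angles), 5L)
  expect_false(anyNA(pop$energy))
  # single-entry library -> all members share identical angles
  sys1 <- make_toy_system(8, entries_per_window = 1, seed = 4)
  model1 <- toy_energy_model(sys1$target, counter = budget_counter(100))
  pop1 <- initial_population(sys1$sequence, sys1$library, model1, 4)
  expect_true(all(apply(pop1$angles, 1, function(r)
    identical(r, pop1$angles[1, ]))))
})

test_that("eval_max = pop_size yields the initial population only", {
  sys <- make_toy_system(8, entries_per_window = 2, seed = 6)
  run <- toy_run(sys, "ea", pop_size = 6, num_child = 3, eval_max = 6,
                 seed = 1, track_diversity = FALSE)
  expect_identical(run$generations, 0L)
  expect_identical(run$eval_count, 6L)
  expect_identical(nrow(run$ensemble$angles), 6L)
  expect_true(all(run$ensemble$meta$generation == 0L))
})

test_that("the budget guard halts a generation mid-way at exactly eval_max", {
  # hand trace (EA, pop 4, child 2, eval_max 9): init scores 4; generation 1
  # scores 2 children (6); generation 2 scores 2 (8); generation 3 scores 1
  # child and the guard stops the second child; a partial generation with
  # one scored child still competes, so 3 generations complete at counter 9
  sys <- make_toy_system(8, entries_per_window = 2, seed = 7)
  run <- toy_run(sys, "ea", pop_size = 4, num_child = 2, eval_max = 9,
                 seed = 2, track_diversity = FALSE)
  expect_identical(run$eval_count, 9L)
  expect_identical(run$generations, 3L)
  expect_identical(nrow(run$ensemble$angles), 4L * 4L)
})

test_that("eval counts equal an instrumented independent counter (EA and MEA)", {
  sys <- make_toy_system(9, entries_per_window = 3, seed = 9)
  for (alg in c("ea", "mea")) {
    shadow <- new.env()
    shadow$calls <- 0L
    model <- toy_energy_model(sys$target)
    inner <- model$score_angles
    model$score_angles <- function(angles, sequence) {
      shadow$calls <- shadow$calls + 1L
      inner(angles, sequence)
    }
    run <- sample_decoys(sys$sequence, sys$library, model, algorithm = alg,
                         pop_size = 8, num_child = 4, eval_max = 400,
                         seed = 5, track_diversity = FALSE)
    expect_identical(run$eval_count, shadow$calls)
    expect_identical(run$eval_count, 400L)
    if (alg == "mea")
      expect_gt(sum(run$logs$greedy_proposals, na.rm = TRUE), 0L)
  }
})

test_that("populations keep constant size and Omega grows by pop_size", {
  sys <- make_toy_system(9, entries_per_window = 3, seed = 10)
  run <- toy_run(sys, "mea", pop_size = 7, num_child = 3, eval_max = 500,
                 seed = 4, track_diversity = FALSE)
  expect_identical(nrow(run$final_population$angles), 7L)
  expect_identical(nrow(run$ensemble$angles),
                   7L * (run$generations + 1L))
  sizes <- table(run$ensemble$meta$generation)
  expect_true(all(sizes == 7L))
})

test_that("best energy is monotone non-increasing across generations", {
  sys <- make_toy_system(10, entries_per_window = 3, seed = 11)
  for (alg in c("ea", "mea")) {
    run <- toy_run(sys, alg, pop_size = 8, num_child = 4, eval_max = 600,
                   seed = 3, track_diversity = FALSE)
    expect_true(all(diff(run$logs$energy_best) <= 1e-12))
  }
})

test_that("identical seed and config give identical runs; seeds differ", {
  sys <- make_toy_system(8, entries_per_window = 3, seed = 13)
  a <- toy_run(sys, "mea", pop_size = 6, num_child = 3, eval_max = 300,
               seed = 42, track_diversity = FALSE)
  b <- toy_run(sys, "mea", pop_size = 6, num_child = 3, eval_max = 300,
               seed = 42, track_diversity = FALSE)
  expect_identical(a$ensemble$angles, b$ensemble$angles)
  expect_identical(a$logs, b$logs)
  expect_identical(a$eval_count, b$eval_count)
  c <- toy_run(sys, "mea", pop_size = 6, num_child = 3, eval_max = 300,
               seed = 43, track_diversity = FALSE)
  expect_false(identical(a$ensemble$angles, c$ensemble$angles))
})

test_that("configuration inconsistencies are reported before any evaluation", {
  sys <- make_toy_system(8, entries_per_window = 2, seed = 1)
  model <- toy_energy_model(sys$target)
  expect_error(sample_decoys(sys$sequence, sys$library, model, pop_size = 1,
                             eval_max = 100, seed = 1), "pop_size")
  expect_error(sample_decoys(sys$sequence, sys$library, model, pop_size = 10,
                             eval_max = 5, seed = 1), "initial population")
  expect_error(sample_decoys(sys$sequence, sys$library, model,
                             pop_size = 4, eval_max = 100), "seed")
  expect_error(sample_decoys("AAAA", sys$library, model, pop_size = 4,
                             eval_max = 100, seed = 1), "library built for")
  expect_identical(budget_spent(model$counter), 0L)
})
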