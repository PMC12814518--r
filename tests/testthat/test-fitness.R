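test_that("fractions divide by the retained column total", {
  d <- toy_design()
  tab <- toy_table(d, input = c(AAA = 30, CCC = 70), final = c(AAA = 1, CCC = 1))
  expect_equal(fractions(tab, "input"), c(AAA = 0.3, CCC = 0.7))
  tab1 <- toy_table(d, input = c(AAA = 12), final = c(AAA = 5))
  expect_equal(fractions(tab1, "input"), c(AAA = 1))
  # simulated table vs direct recomputation
  rho <- toy_rho(library_design(), nv = 30, seed = 7)
  sim <- run_selection(sim_params(library_design(), rho, read_depth = 1e4,
                                  bottleneck = 1e4, seed = 7))
  f <- fractions(sim$table, "P2")
  expect_equal(f, sim$table$counts[, "P2"] / sum(sim$table$counts[, "P2"]))
  expect_equal(sum(f), 1, tolerance = 1e-9)
  # zero-total column fails
  tabz <- toy_table(d, input = c(AAA = 5, CCC = 5), final = c(AAA = 0, CCC = 0))
  expect_error(fractions(tabz, "P1"), "zero total")
})

test_that("fitness score is the log10 frequency ratio with a depleted sentinel", {
  expect_equal(fitness_score(0.37, 0.37), 0)
  expect_equal(fitness_score(0.01, 0.001), -1.0)
  expect_equal(fitness_score(0.001, 0.46), log10(460))
  expect_true(is.na(fitness_score(0.05, 0)))
  expect_error(fitness_score(0, 0.1), "positive")
  # strictly increasing in f_final, strictly decreasing in f_input
  expect_true(all(diff(fitness_score(0.01, c(0.001, 0.01, 0.1, 0.5))) > 0))
  expect_true(all(diff(fitness_score(c(0.001, 0.01, 0.1, 0.5), 0.01)) < 0))
})

test_that("fold propagation is output over input", {
  expect_equal(fold_propagation(1e5, 1e5), 1)
  expect_equal(fold_propagation(1e8, 1e5), 1e3)
  expect_error(fold_propagation(1e5, 0), "positive")
  # deterministic two-arm run: a 1000x propagation gap shows up as a
  # >=1000x fold-propagation ratio on the first passage
  d <- toy_design()
  run_arm <- function(r) {
    p <- sim_params(d, c(V = r), input_abundance = c(V = 1),
                    bottleneck = Inf, read_depth = 1e3, seed = 1)
    run_selection(p)$titers$fold_propagation[1]
  }
  expect_gte(run_arm(1000) / run_arm(1), 1000)
})

test_that("classification partitions variants and applies the -1.0 bound inclusively", {
  d <- toy_design()
  # f_input(A)=0.1, f_final(A)=0.01 -> fitness exactly -1.0 -> lowered
  tab <- toy_table(d,
                   input = c(AAA = 10, CCC = 90),
                   final = c(AAA = 1, CCC = 99))
  fit <- pancs_fit(tab, min_input_reads = 10)
  r <- fit$records
  expect_equal(r$fitness[r$variant == "AAA"], -1.0)
  expect_true(r$lowered_assembly_predicted[r$variant == "AAA"])
  expect_equal(r$outcome_class[r$variant == "AAA"], "negative")
  expect_equal(r$outcome_class[r$variant == "CCC"], "positive")
  expect_false(r$lowered_assembly_predicted[r$variant == "CCC"])

  # all depleted except one carrier -> lowered-assembly fraction counts them
  tab2 <- toy_table(d,
                    input = c(AAA = 50, CCC = 50, DDD = 50),
                    final = c(AAA = 0, CCC = 0, DDD = 10))
  fit2 <- pancs_fit(tab2, min_input_reads = 10)
  s2 <- summary(fit2)
  expect_equal(s2$n_depleted, 2)
  expect_equal(s2$fraction_lowered_assembly, 2 / 3)
  expect_true(all(fit2$records$outcome_class %in%
                    c("positive", "negative", "depleted")))

  # partition is exhaustive and mutually exclusive on simulated data
  rho <- toy_rho(library_design(), nv = 300, seed = 12, spread = 3)
  sim <- run_selection(sim_params(library_design(), rho, read_depth = 1e5,
                                  bottleneck = 1e4, seed = 12))
  fit3 <- pancs_fit(sim$table)
  r3 <- fit3$records
  expect_equal(sum(r3$outcome_class == "depleted"),
               sum(fit3$table$counts[, "P3"] == 0))
  expect_equal(table(r3$outcome_class)[["depleted"]] +
                 sum(!is.na(r3$fitness)), nrow(r3))
  expect_true(all((r3$outcome_class == "positive") == (!is.na(r3$fitness) &
                                                         r3$fitness > 0)))
})

test_that("fitness recovers the true propagation landscape", {
  d <- library_design()
  rho <- toy_rho(d, nv = 500, seed = 31, spread = 3)
  sim <- run_selection(sim_params(d, rho, read_depth = 1e6,
                                  bottleneck = 1e5, seed = 31))
  fit <- pancs_fit(sim$table)
  r <- fit$records[!is.na(fit$records$fitness), ]
  rs <- stats::cor(log10(rho[r$variant]), r$fitness, method = "spearman")
  expect_gte(rs, 0.8)
})

test_that("arm comparison reports ratios and rescued variants", {
  d <- toy_design()
  tab <- toy_table(d,
                   input = c(AAA = 20, CCC = 30, DDD = 50),
                   final = c(AAA = 0, CCC = 10, DDD = 90))
  fit <- pancs_fit(tab)
  cmp_same <- compare_arms(fit, fit)
  expect_equal(cmp_same$positive_ratio, 1)
  expect_length(cmp_same$rescued, 0)

  tab_plus <- toy_table(d,
                        input = c(AAA = 20, CCC = 30, DDD = 50),
                        final = c(AAA = 5, CCC = 20, DDD = 75))
  fit_plus <- pancs_fit(tab_plus)
  cmp <- compare_arms(fit, fit_plus)
  dep_minus <- fit$records$variant[fit$records$outcome_class == "depleted"]
  dep_plus <- fit_plus$records$variant[fit_plus$records$outcome_class == "depleted"]
  expect_equal(cmp$rescued, sort(setdiff(dep_minus, dep_plus)))
  expect_equal(cmp$depleted_change, length(dep_plus) - length(dep_minus))

  tab_other <- toy_table(d, input = c(AAA = 20, CCC = 30),
                         final = c(AAA = 1, CCC = 1))
  expect_error(compare_arms(fit, pancs_fit(tab_other)), "different variant")
})

test_that("chaperonin buffering raises the positive fraction on shared seeds", {
  d <- library_design()
  wins <- 0L
  n <- 20
  for (s in seq_len(n)) {
    ex <- simulate_experiment(design = d,
                              truth = ground_truth(d, seed = s,
                                                   groels_buffer = 0.5),
                              read_depth = 2e5, seed = s)
    sm <- summary(pancs_fit(ex$minus$table))
    sp <- summary(pancs_fit(ex$plus$table))
    if (sp$fraction_positive >= sm$fraction_positive) wins <- wins + 1L
  }
  expect_gte(wins / n, 0.95)
})

test_that("coef and summary expose the records", {
  d <- toy_design()
  tab <- toy_table(d, input = c(AAA = 20, CCC = 80),
                   final = c(AAA = 40, CCC = 60))
  fit <- pancs_fit(tab)
  co <- coef(fit)
  expect_named(co, c("AAA", "CCC"))
  expect_equal(unname(co["AAA"]), log10(0.4 / 0.2))
  expect_output(print(fit), "positive")
  expect_output(print(summary(fit)), "analyzed")
})
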