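test_that("configuration invariants are enforced with named errors", {
  expect_s3_class(simulation_config(seed = 1), "simulation_config")
  expect_error(
    simulation_config(outcome_probs = list(
      control = c(0.5, 0.2, 0.1, 0.1), fungi = c(1, 0, 0, 0),
      halfmix = c(1, 0, 0, 0), nematodes = c(1, 0, 0, 0))),
    "outcome_probs\\[control\\]")
  expect_error(simulation_config(nb_dispersion = 0), "nb_dispersion")
  expect_error(simulation_config(block_sd = -0.1), "block_sd")
  expect_error(
    simulation_config(rate_ratios = list(control = 2, fungi = 1,
                                         halfmix = 1, nematodes = 1)),
    "control must equal 1")
  expect_error(
    simulation_config(community_taxon_means = c(a = -1)),
    "community_taxon_means")
  expect_error(simulation_config(treatments = c("fungi", "control")),
               "control")
})

test_that("degenerate outcome probabilities give deterministic outcomes", {
  cfg <- simulation_config(
    seed = 4, n_blocks = 4,
    outcome_probs = list(control = c(1, 0, 0, 0), fungi = c(1, 0, 0, 0),
                         halfmix = c(1, 0, 0, 0),
                         nematodes = c(1, 0, 0, 0)))
  rec <- simulate_destructive(cfg, n_records = 500)
  expect_true(all(rec$outcome[rec$treatment == "control"] == "alive"))
})

test_that("simulated outcome and stage frequencies converge to the inputs", {
  cfg <- simulation_config(seed = 101)
  rec <- simulate_destructive(cfg, n_records = 1e5)
  hm <- rec[rec$treatment == "halfmix", ]
  emp <- prop.table(table(factor(hm$outcome, outcome_levels())))
  expect_equal(as.numeric(emp),
               unname(cfg$outcome_probs[["halfmix"]]),
               tolerance = 0.01 / max(cfg$outcome_probs[["halfmix"]]))
  expect_true(max(abs(as.numeric(emp) -
                        cfg$outcome_probs[["halfmix"]])) < 0.01)
  emp_stage <- prop.table(table(factor(rec$stage, stage_levels())))
  expect_true(max(abs(as.numeric(emp_stage) - cfg$stage_probs)) < 0.01)
  # goodness-of-fit not rejected at alpha = 0.01 in most seeds
  pvals <- vapply(1:20, function(s) {
    r <- simulate_destructive(simulation_config(seed = s),
                              n_records = 2e4)
    h <- r[r$treatment == "halfmix", ]
    suppressWarnings(stats::chisq.test(
      table(factor(h$outcome, outcome_levels())),
      p = cfg$outcome_probs[["halfmix"]])$p.value)
  }, numeric(1))
  expect_gte(mean(pvals > 0.01), 0.95)
})

test_that("generation is reproducible under a fixed seed", {
  cfg <- simulation_config(seed = 7)
  expect_identical(simulate_destructive(cfg), simulate_destructive(cfg))
  expect_identical(simulate_emergence(cfg), simulate_emergence(cfg))
  expect_identical(simulate_community(cfg)$counts,
                   simulate_community(cfg)$counts)
  # different substreams: changing one dataset's use does not change others
  expect_false(identical(simulate_destructive(cfg)$depth_cm[1:5],
                         simulate_destructive(
                           simulation_config(seed = 8))$depth_cm[1:5]))
})

test_that("destructive records respect layout, vocab and sign conventions", {
  cfg <- simulation_config(seed = 12, n_blocks = 6)
  rec <- simulate_destructive(cfg)
  expect_true(all(rec$treatment %in% treatment_levels()))
  expect_true(all(rec$stage %in% stage_levels()))
  expect_true(all(rec$outcome %in% outcome_levels()))
  expect_true(all(rec$dist_bole_cm >= 0))
  expect_lt(mean(rec$depth_cm > 0), 0.05)  # small positive tail only
  expect_setequal(unique(rec$block), sprintf("B%02d", 1:6))
})

test_that("emergence counts recover configured rate ratios and variance", {
  cfg <- simulation_config(seed = 21, n_blocks = 1e4, block_sd = 0,
                           treatments = c("control", "nematodes"),
                           rate_ratios = list(control = 1,
                                              nematodes = 0.322))
  em <- simulate_emergence(cfg)
  means <- tapply(em$emerged, em$treatment, mean)
  expect_equal(unname(means[["nematodes"]] / means[["control"]]), 0.322,
               tolerance = 0.02 / 0.322)
  # NB2 mean-variance relation at fixed block effect
  mu <- exp(cfg$emergence_intercept)
  v_expect <- mu + mu^2 / cfg$nb_dispersion
  v_emp <- var(em$emerged[em$treatment == "control"])
  expect_equal(v_emp, v_expect, tolerance = 0.1)
})

test_that("emergence approaches the Poisson limit at huge dispersion", {
  cfg <- simulation_config(seed = 33, n_blocks = 5000, block_sd = 0,
                           nb_dispersion = 1e8,
                           treatments = "control",
                           outcome_probs = list(control = c(1, 0, 0, 0)),
                           rate_ratios = list(control = 1))
  em <- simulate_emergence(cfg)
  expect_equal(mean(em$emerged), exp(cfg$emergence_intercept),
               tolerance = 0.02)
  expect_equal(var(em$emerged) / mean(em$emerged), 1, tolerance = 0.06)
})

test_that("emergence layout is a complete randomised block design", {
  cfg <- simulation_config(seed = 2, n_blocks = 7)
  em <- simulate_emergence(cfg)
  expect_equal(nrow(em), 7 * 4)
  expect_true(all(table(em$block, em$treatment) == 1))
  expect_true(all(em$emerged >= 0))
})

test_that("community generator honours means, effects and degenerate cases", {
  cfg <- simulation_config(seed = 5, n_blocks = 200)
  cm <- simulate_community(cfg)
  expect_equal(unname(colMeans(cm$counts)),
               unname(cfg$community_taxon_means), tolerance = 0.05)
  zero <- simulate_community(
    simulation_config(seed = 5, community_taxon_means = c(a = 0, b = 0)))
  expect_true(all(zero$counts == 0))
  eff <- simulation_config(seed = 6, n_blocks = 100,
                           community_effect = list(control = 1, fungi = 5,
                                                   halfmix = 1,
                                                   nematodes = 1))
  cme <- simulate_community(eff)
  m_f <- colMeans(cme$counts[cme$treatment == "fungi", ])
  m_c <- colMeans(cme$counts[cme$treatment == "control", ])
  expect_equal(unname(m_f / m_c), rep(5, ncol(cme$counts)),
               tolerance = 0.1)
})

test_that("dataset CSV round-trips preserve the generated values", {
  cfg <- simulation_config(seed = 44, n_blocks = 4)
  dir <- withr::local_tempdir()
  paths <- write_simulated_datasets(cfg, dir)
  rec <- read_destructive_csv(paths[["destructive"]])
  expect_equal(rec$outcome, simulate_destructive(cfg)$outcome)
  em <- read_emergence_csv(paths[["emergence"]])
  expect_equal(em$emerged, simulate_emergence(cfg)$emerged)
  cm <- read_community_csv(paths[["community"]])
  expect_equal(unname(cm$counts), unname(simulate_community(cfg)$counts))
})
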