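quick_cfg <- function(...) {
  study_config(n_values = 100L, J_values = 4L, K_values = 3L, R = 2L, ...)
}

test_that("replications are deterministic and separated by stream", {
  cfg <- quick_cfg()
  pop <- generate_population(grm_condition(100, 4, 3, R = 2))
  r1 <- run_replication(pop, 1, cfg)
  r1b <- run_replication(pop, 1, cfg)
  expect_identical(r1, r1b)
  r2 <- run_replication(pop, 2, cfg)
  expect_false(identical(r1$rmse_a, r2$rmse_a))
  expect_identical(r1$status, "ok")
})

test_that("a single-replication condition aggregates to itself", {
  cfg <- study_config(n_values = 100L, J_values = 4L, K_values = 3L, R = 1L)
  res <- run_condition(grm_condition(100, 4, 3, R = 1), cfg)
  expect_identical(nrow(res$per_replication), 1L)
  for (col in c("rmse_a", "rmse_theta", "rmse_a_std_fpc")) {
    expect_equal(res$per_condition[[col]], res$per_replication[[col]])
  }
  expect_equal(res$per_condition$r_bar, res$per_replication$r)
})

test_that("condition aggregates equal recomputation from replication rows", {
  res <- cached_condition(100, 5, 4, R = 4)
  pr <- res$per_replication
  pc <- res$per_condition
  expect_identical(nrow(pr), 4L)
  expect_equal(pc$rmse_a, mean(pr$rmse_a))
  expect_equal(pc$rmse_theta_fpc, mean(pr$rmse_theta_fpc))
  expect_equal(pc$r_bar, fisher_mean_r(pr$r))
  expect_equal(pc$conv_rate, mean(pr$converged))
  # EAP shrinkage should hold on every replication: rmse_theta < 1 implies
  # the estimates sit closer to the prior mean than the truths on average
  expect_true(all(pr$status == "ok"))
})

test_that("the grid runner covers the Cartesian product deterministically", {
  cfg <- study_config(n_values = c(100L, 150L), J_values = c(3L, 5L),
                      K_values = c(3L, 4L), R = 3L)
  study <- run_grid(cfg, progress = FALSE)
  expect_s3_class(study, "grm_study")
  expect_identical(nrow(study$per_replication), 24L)
  expect_identical(nrow(study$per_condition), 8L)
  expect_identical(study$manifest$n_cells, 8L)
  # serial and parallel execution agree exactly
  cfg2 <- study_config(n_values = c(100L, 150L), J_values = c(3L, 5L),
                       K_values = c(3L, 4L), R = 3L, workers = 2L)
  study2 <- run_grid(cfg2, progress = FALSE)
  expect_equal(study$per_replication, study2$per_replication)
  expect_equal(study$per_condition, study2$per_condition)
})

test_that("checkpointing resumes from written cells", {
  dir <- withr::local_tempdir()
  cfg <- study_config(n_values = 100L, J_values = c(3L, 4L), K_values = 3L,
                      R = 2L, checkpoint_dir = dir)
  s1 <- run_grid(cfg, progress = FALSE)
  expect_length(list.files(dir, pattern = "^cell_.*csv$"), 2L)
  s2 <- run_grid(cfg, progress = FALSE)  # read back from checkpoints
  expect_equal(s1$per_condition, s2$per_condition)
  expect_equal(s1$per_replication$rmse_a, s2$per_replication$rmse_a)
})

test_that("the default configuration spans the full reference grid", {
  cfg <- study_config()
  expect_identical(length(cfg$n_values) * length(cfg$J_values) *
                     length(cfg$K_values), 440L)
  expect_identical(cfg$R, 100L)
  expect_identical(cfg$base_seed, 123L)
  expect_identical(cfg$n_values, seq(500L, 1500L, by = 100L))
})

test_that("saturation summaries scan J means for diminishing returns", {
  pc <- tidyr::expand_grid(n = c(100L, 200L), K = 3L, J = c(5L, 10L, 15L, 20L))
  pc$status <- "ok"
  # constant metric: saturation at the second J value
  pc$rmse_theta_fpc <- 0.5
  sat <- summarize_saturation(pc)
  expect_true(all(sat$saturation_J == 10L))
  # strictly improving by 0.1 per step: never saturates in range
  pc$rmse_theta_fpc <- rep(seq(0.8, 0.5, by = -0.1), times = 2)
  sat <- summarize_saturation(pc)
  expect_true(all(is.na(sat$saturation_J)))
  expect_error(summarize_saturation(dplyr::filter(pc, J < 15)),
               class = "grmsim_invalid_request")
  expect_error(summarize_saturation(pc, metric = "no_such"),
               class = "grmsim_invalid_request")
})

test_that("study objects expose tidy and glance summaries", {
  res <- cached_condition(100, 5, 4, R = 4)
  study <- structure(list(per_replication = res$per_replication,
                          per_condition = res$per_condition,
                          config = study_config(R = 4),
                          manifest = list(n_cells = 1L)),
                     class = "grm_study")
  expect_identical(tidy(study), res$per_condition)
  gl <- glance(study)
  expect_identical(gl$n_cells, 1L)
  expect_identical(gl$n_replications, 4L)
  expect_equal(gl$min_r_bar, res$per_condition$r_bar)
})
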