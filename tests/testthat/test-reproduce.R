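test_that("run_study reproduces published summaries and is order-stable", {
  coh <- load_cohort()
  rep <- run_study(coh)
  s <- rep$summaries
  fu_adc_t <- s[s$biomarker == "adc_followup_mm2s" & s$group == "therapy", ]
  expect_equal(round(fu_adc_t$mean * 1e3, 2), 0.90)
  expect_equal(round(fu_adc_t$sd * 1e3, 2), 0.13)
  fu_mtv_c <- s[s$biomarker == "mtv_followup_mm3" & s$group == "control", ]
  expect_equal(round(fu_mtv_c$mean, 1), 573.5)

  # deterministic: identical cohort gives identical report
  rep2 <- run_study(coh)
  expect_identical(rep$tests$p_value, rep2$tests$p_value)
  expect_identical(rep$correlations$rho, rep2$correlations$rho)

  # baseline balance precedes effect tests in the fixed analysis order
  expect_equal(unique(rep$tests$comparison)[1], "intergroup_baseline")
  expect_error(run_study(coh[coh$group == "therapy", ]), "both groups")
})

test_that("relabeling the groups flips effect signs, preserves p-values", {
  coh <- load_cohort()
  swapped <- coh
  swapped$group <- ifelse(coh$group == "therapy", "control", "therapy")
  a <- run_study(coh); b <- run_study(swapped)
  # intergroup tests are symmetric in the group labels
  inter <- a$tests$comparison != "intragroup"
  expect_equal(b$tests$p_value[inter], a$tests$p_value[inter],
               tolerance = 1e-12)
  # intragroup tests travel with the relabeled animals
  ia <- a$tests[!inter, ]; ib <- b$tests[!inter, ]
  for (i in seq_len(nrow(ia))) {
    other <- ifelse(ia$group[i] == "therapy", "control", "therapy")
    expect_equal(ib$p_value[ib$biomarker == ia$biomarker[i] &
                              ib$group == other], ia$p_value[i],
                 tolerance = 1e-12)
  }
  da <- aggregate(d_ttl ~ group, compute_deltas(coh), mean)
  db <- aggregate(d_ttl ~ group, compute_deltas(swapped), mean)
  expect_equal(db$d_ttl[db$group == "therapy"],
               da$d_ttl[da$group == "control"])
})

test_that("comparison against published values is consistent on the fixtures", {
  rep <- run_study(load_cohort())
  cmp <- compare_to_published(rep)
  expect_true(attr(cmp, "all_consistent"))
  # the only non-matching rows are the documented whitelisted correlations
  expect_true(all(cmp$whitelisted[!cmp$match]))
  expect_true(all(nzchar(cmp$note[!cmp$match])))
  # every summary row matches at printed precision outright
  expect_true(all(cmp$match[cmp$type == "summary"]))
})

test_that("report rendering round-trips JSON and tabulates every statistic", {
  rep <- run_study(load_cohort())
  dir <- tempfile()
  files <- render_report(rep, dir)
  got <- jsonlite::read_json(files[["json"]], simplifyVector = TRUE)
  expect_true(got$all_consistent)
  expect_equal(nrow(got$comparison), nrow(reference_values()))
  expect_equal(got$correlations$rho, rep$correlations$rho, tolerance = 1e-12)
  md <- readLines(files[["md"]])
  expect_equal(sum(grepl("^\\| [a-z0-9_]+[:~]", md)), nrow(reference_values()))
  unlink(dir, recursive = TRUE)
})

test_that("phantom pipeline is seed-deterministic end to end", {
  cfg <- cohort_sim_config(n_therapy = 3, n_control = 3, seed = 5)
  a <- run_phantom_pipeline(cfg, seed = 5)
  b <- run_phantom_pipeline(cfg, seed = 5)
  expect_identical(a$measured, b$measured)
  expect_identical(a$report$tests$p_value, b$report$tests$p_value)
  c2 <- run_phantom_pipeline(cfg, seed = 6)
  expect_false(identical(a$measured$ttl_followup, c2$measured$ttl_followup))
})

test_that("noiseless phantom pipeline recovers the configured effects", {
  pp <- run_phantom_pipeline(cohort_sim_config(seed = 11), seed = 11)
  # TTL: uniform tumor, truth masks -> exact ratio recovery
  expect_equal(pp$measured$ttl_baseline, pp$target$ttl_baseline,
               tolerance = 1e-12)
  expect_equal(pp$measured$ttl_followup, pp$target$ttl_followup,
               tolerance = 1e-12)
  # ADC: noiseless mono-exponential -> machine precision
  expect_equal(pp$measured$adc_followup_mm2s, pp$target$adc_followup_mm2s,
               tolerance = 1e-9)
  # MTV: voxelized sphere vs target volume, within voxelization error,
  # where the target lies in the representable radius range
  rep_ok <- pp$target$mtv_followup_mm3 > 30 & pp$target$mtv_followup_mm3 < 1000
  relerr <- abs(pp$measured$mtv_followup_mm3 - pp$target$mtv_followup_mm3) /
    pp$target$mtv_followup_mm3
  expect_lt(max(relerr[rep_ok]), 0.10)
  # group-level delta effects carried through the image pipeline
  dm <- compute_deltas(pp$measured); dt <- compute_deltas(pp$target)
  expect_equal(mean(dm$d_ttl[dm$group == "therapy"]),
               mean(dt$d_ttl[dt$group == "therapy"]), tolerance = 1e-12)
  expect_equal(mean(dm$d_adc_mm2s[dm$group == "control"]),
               mean(dt$d_adc_mm2s[dt$group == "control"]), tolerance = 1e-9)
})

test_that("zero-effect phantom cohorts rarely reach significance", {
  hits <- 0L
  reps <- 200
  for (s in seq_len(reps)) {
    d <- compute_deltas(generate_cohort(null_cohort_config(seed = s)))
    p <- mann_whitney_exact(d$d_ttl[d$group == "therapy"],
                            d$d_ttl[d$group == "control"])$p_value
    hits <- hits + (p < 0.05)
  }
  expect_gte((reps - hits) / reps, 0.90)
})
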