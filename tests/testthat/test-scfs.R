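# Force-curve analytics: delimited-format I/O, linear baseline correction on
# the separated retract tail, F_max extraction and group summaries.

test_that("curve files round-trip exactly and reject malformed input", {
  g <- gen_force_curve(7.5, noise_sd_nN = 0.05, drift_nN_per_um = 0.1,
                       contact_time_s = 10, seed = 6)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_curve(g$curve, tmp)
  back <- load_curves(tmp)[[1]]
  expect_identical(back$retract$force_nN, g$curve$retract$force_nN)
  expect_identical(back$approach$separation_um, g$curve$approach$separation_um)
  expect_identical(back$contact_time_s, 10)
  expect_identical(back$metadata$variant, "ScFlo11A")

  # missing segment column -> format error
  lines <- readLines(tmp)
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(gsub(",segment", ",seg", lines, fixed = TRUE), bad)
  expect_error(load_curves(bad), "missing column")

  # missing contact-time header
  writeLines(lines[!grepl("contact_time_s", lines)], bad)
  expect_error(load_curves(bad), "contact_time_s")

  # malformed numeric row reported with its line number
  lines2 <- lines
  lines2[20] <- "oops,1.0,retract"
  writeLines(lines2, bad)
  expect_error(load_curves(bad), "line 20")
})

test_that("a directory of curves loads in sorted-path order", {
  dir <- withr::local_tempdir()
  for (ct in c(20, 0.5, 5)) {
    g <- gen_force_curve(2, contact_time_s = ct, seed = round(10 * ct))
    write_curve(g$curve, file.path(dir, sprintf("curve_%04.1f.csv", ct)))
  }
  curves <- load_curves(dir)
  expect_length(curves, 3L)
  expect_identical(vapply(curves, `[[`, numeric(1), "contact_time_s"),
                   c(0.5, 5, 20))  # 00.5 < 05.0 < 20.0
})

test_that("baseline correction removes drift and offsets exactly", {
  clean <- gen_force_curve(5, noise_sd_nN = 0, drift_nN_per_um = 0,
                           seed = 1)$curve
  corr <- baseline_correct(clean)
  expect_lt(max(abs(corr$retract$force_nN - clean$retract$force_nN)), 1e-12)

  drifted <- gen_force_curve(5, noise_sd_nN = 0, drift_nN_per_um = 0.2,
                             seed = 1)$curve
  dc <- baseline_correct(drifted)
  n <- nrow(dc$retract)
  tail_idx <- (n - floor(0.2 * n) + 1):n
  expect_lt(abs(mean(dc$retract$force_nN[tail_idx])), 1e-9)
  expect_equal(attr(dc, "baseline")[["slope_nN_per_um"]], 0.2,
               tolerance = 1e-9)

  offset <- clean
  offset$retract$force_nN <- offset$retract$force_nN + 2
  offset$approach$force_nN <- offset$approach$force_nN + 2
  oc <- baseline_correct(offset)
  expect_lt(max(abs(oc$retract$force_nN - corr$retract$force_nN)), 1e-9)

  expect_error(baseline_correct(clean, tail_fraction = 0.02),
               "fewer than 10")
})

test_that("F_max is recovered to machine precision on noise-free curves", {
  for (f in c(0, 0.5, 5, 25)) {
    g <- gen_force_curve(f, noise_sd_nN = 0, drift_nN_per_um = 0.15, seed = 2)
    r <- extract_fmax(baseline_correct(g$curve))
    expect_equal(r$fmax_nN, f, tolerance = 1e-10)
    if (f > 0)
      expect_equal(r$min_separation_um, g$truth$min_separation_um)
  }
  # flat zero retract
  flat <- gen_force_curve(0, noise_sd_nN = 0, seed = 3)
  expect_identical(extract_fmax(baseline_correct(flat$curve))$fmax_nN, 0)
})

test_that("F_max is invariant under constant force offsets", {
  g <- gen_force_curve(8, noise_sd_nN = 0.05, seed = 4)$curve
  shifted <- g
  shifted$retract$force_nN <- shifted$retract$force_nN + 3.7
  shifted$approach$force_nN <- shifted$approach$force_nN + 3.7
  f1 <- extract_fmax(baseline_correct(g))$fmax_nN
  f2 <- extract_fmax(baseline_correct(shifted))$fmax_nN
  expect_equal(f1, f2, tolerance = 1e-9)
})

test_that("noisy drifting curves stay within 0.5 nN of truth", {
  errs <- vapply(1:50, function(s) {
    g <- gen_force_curve(5, noise_sd_nN = 0.1, drift_nN_per_um = 0.2,
                         seed = s)
    extract_fmax(baseline_correct(g$curve))$fmax_nN - 5
  }, numeric(1))
  expect_lt(max(abs(errs)), 0.5)
})

test_that("group summaries use sample SD and flag small groups", {
  expect_warning(s <- summarize_groups(c(3, 5), c("a", "a")),
                 "fewer than 15")
  expect_equal(s$mean_nN, 4)
  expect_equal(s$sd_nN, sqrt(2))

  expect_warning(
    expect_warning(s1 <- summarize_groups(c(3, 5, 7), c("a", "a", "b")),
                   "single-measurement"),
    "fewer than 15")
  expect_identical(s1$sd_nN[s1$group == "b"], 0)

  expect_silent(s15 <- summarize_groups(rep(4.2, 15), rep("a", 15)))
  expect_identical(s15$sd_nN, 0)
  expect_identical(s15$n, 15L)
})

test_that("adhesion kinetics summarise per contact time, ascending", {
  times <- rep(c(0.5, 1, 5, 20), each = 12)
  truth_mean <- 2 + 8 * (times / 20)^0.4
  set.seed(9)
  fmax <- truth_mean + rnorm(length(times), 0, 0.3)
  k <- adhesion_kinetics(fmax, times)
  expect_identical(k$contact_time_s, c(0.5, 1, 5, 20))
  expect_true(all(diff(k$mean_nN) > 0))
  expect_identical(k$n, rep(12L, 4))

  expect_error(adhesion_kinetics(fmax, rep(20, length(fmax))),
               "two distinct")

  # equal truths: recovered means within the noise band of each other
  set.seed(10)
  flatf <- 6 + rnorm(length(times), 0, 0.3)
  kf <- adhesion_kinetics(flatf, times)
  expect_lt(diff(range(kf$mean_nN)), 4 * 0.3 / sqrt(12))
})

test_that("analyze_curves yields one tidy row per curve", {
  curves <- lapply(1:3, function(s)
    gen_force_curve(s, contact_time_s = s, noise_sd_nN = 0.02,
                    variant = "KpFlo11A", seed = s)$curve)
  tab <- analyze_curves(curves)
  expect_identical(nrow(tab), 3L)
  expect_identical(tab$variant, rep("KpFlo11A", 3))
  expect_equal(tab$fmax_nN, 1:3, tolerance = 0.2)
})

test_that("tabular F_max exports parse with flexible column headings", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Interaction,Contact time [s],Fmax (nN)",
               "ScFlo11A-ScFlo11A,20,12.1",
               "ScFlo11A-ScFlo11A,20,14.9",
               "dA-dA,20,1.3"), tmp)
  tab <- load_fmax_table(tmp)
  expect_identical(tab$fmax_nN, c(12.1, 14.9, 1.3))
  expect_identical(tab$contact_time_s, rep(20, 3))
  expect_identical(tab$group, c("ScFlo11A-ScFlo11A", "ScFlo11A-ScFlo11A",
                                "dA-dA"))
  expect_equal(mean(tab$fmax_nN[tab$group == "ScFlo11A-ScFlo11A"]), 13.5)
  expect_error(load_fmax_table(tmp, fmax_col = "bogus"), "not found")
})
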