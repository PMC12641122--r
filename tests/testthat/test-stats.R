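test_that("weekly-to-monthly aggregation is two-stage and missing-aware", {
  tab <- data.frame(
    subject_id = "m1", genotype = "WT", age_month = 6,
    age_week = rep(1:4, 2),
    channel = rep(c("e1", "e2"), each = 4),
    metric = "fei", band_label = "35-45 Hz",
    value = c(1.0, 1.2, NA, 1.1, 0.9, 0.9, 0.9, 0.9))
  agg <- weekly_to_monthly(tab)
  e1 <- agg$electrode_month$value[agg$electrode_month$channel == "e1"]
  expect_equal(e1, mean(c(1.0, 1.2, 1.1)))          # NA excluded
  expect_equal(agg$mouse_month$value, mean(c(e1, 0.9)))
  # mouse with electrode-months 0.9 / 1.1 -> 1.0
  tab2 <- data.frame(subject_id = "m2", genotype = "WT", age_month = 6,
                     age_week = 1, channel = c("e1", "e2"), metric = "fei",
                     band_label = "b", value = c(0.9, 1.1))
  expect_equal(weekly_to_monthly(tab2)$mouse_month$value, 1.0)
  # single week: passthrough
  tab3 <- tab2[1, ]
  expect_equal(weekly_to_monthly(tab3)$mouse_month$value, 0.9)
  # idempotence: aggregating the electrode-month table again changes nothing
  em <- agg$electrode_month
  em$age_week <- 1
  agg2 <- weekly_to_monthly(em)
  expect_equal(sort(agg2$mouse_month$value), sort(agg$mouse_month$value))
})

test_that("rmcorr: parallel lines give r_rm = 1; brute-force ANCOVA oracle", {
  p <- data.frame(subject = rep(c("a", "b"), each = 4), x = rep(1:4, 2),
                  y = c(1:4 + 10, 1:4 + 20))
  r <- rmcorr(p)
  expect_equal(r$r_rm, 1, tolerance = 1e-12)
  expect_equal(r$dof, 8 - 2 - 1)
  # oracle: explicit design-matrix least squares
  set.seed(5)
  p2 <- data.frame(subject = rep(letters[1:3], each = 8),
                   x = rnorm(24), y = rnorm(24))
  r2 <- rmcorr(p2)
  X1 <- cbind(model.matrix(~ factor(p2$subject) - 1), p2$x)
  X0 <- model.matrix(~ factor(p2$subject) - 1)
  rss1 <- sum((p2$y - X1 %*% qr.solve(X1, p2$y))^2)
  rss0 <- sum((p2$y - X0 %*% qr.solve(X0, p2$y))^2)
  slope <- qr.solve(X1, p2$y)[4]
  r_o <- unname(sign(slope) * sqrt((rss0 - rss1) / rss0))
  expect_equal(r2$r_rm, r_o, tolerance = 1e-10)
  t_o <- r_o * sqrt(r2$dof / (1 - r_o^2))
  expect_equal(r2$p, 2 * pt(-abs(t_o), r2$dof), tolerance = 1e-10)
  expect_true(r2$ci95[1] <= r2$r_rm && r2$r_rm <= r2$ci95[2])
})

test_that("rmcorr is invariant under per-subject centering and drops flat subjects", {
  set.seed(6)
  p <- data.frame(subject = rep(1:4, each = 6), x = rnorm(24), y = rnorm(24))
  r0 <- rmcorr(p)$r_rm
  pc <- do.call(rbind, lapply(split(p, p$subject), function(d) {
    d$x <- d$x - mean(d$x); d$y <- d$y - mean(d$y); d
  }))
  expect_equal(rmcorr(pc)$r_rm, r0, tolerance = 1e-12)
  # a zero-x-variance subject is dropped with a note
  pz <- rbind(p, data.frame(subject = 9, x = rep(2, 3), y = rnorm(3)))
  rz <- rmcorr(pz)
  expect_equal(rz$r_rm, r0, tolerance = 1e-12)
  expect_true("9" %in% rz$dropped_subjects)
  expect_error(rmcorr(data.frame(subject = 1, x = 1:5, y = 1:5)),
               ">= 2 subjects")
})

test_that("rmcorr null calibration: type-I error near nominal", {
  set.seed(7)
  ps <- replicate(200, {
    d <- data.frame(subject = rep(1:5, each = 6), x = rnorm(30), y = rnorm(30))
    rmcorr(d)$p
  })
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.03)
})

test_that("matching rules: join cardinality, missing and zero-rate exclusion", {
  fei_m <- expand.grid(subject_id = "m1", channel = paste0("e", 1:4),
                       age_month = 3:11, stringsAsFactors = FALSE)
  fei_m$value <- rnorm(nrow(fei_m), 1, 0.05)
  pac_m <- fei_m; pac_m$value <- runif(nrow(pac_m), 0, 0.05)
  pairs <- match_fei_pac(fei_m, pac_m)
  expect_equal(nrow(pairs), 36L)              # 9 months x 4 channels
  fei_m2 <- fei_m; fei_m2$value[5] <- NA
  expect_equal(nrow(match_fei_pac(fei_m2, pac_m)), 35L)
  # weekly spikes: zero-rate weeks excluded, channel means taken
  fw <- data.frame(subject_id = "m1", age_week = rep(1:3, each = 3),
                   channel = rep(paste0("e", 1:3), 3),
                   value = c(1.0, 1.1, 1.2, rep(1, 6)))
  rw <- data.frame(subject_id = "m1", age_week = 1:3, rate = c(0.05, 0, 0.02))
  pr <- match_fei_spikes(fw, rw)
  expect_equal(nrow(pr), 2L)                  # week 2 dropped
  expect_equal(pr$x[pr$y == 0.05], 1.1)       # mean of the three channels
  # monthly PAC vs monthly mean rate
  pm <- data.frame(subject_id = "m1", age_month = c(3, 3, 4),
                   channel = c("e1", "e2", "e1"), value = c(0.02, 0.04, 0.05))
  rwm <- data.frame(subject_id = "m1", age_week = 1:4,
                    age_month = c(3, 3, 4, 4), rate = c(0.1, 0.3, 0, 0))
  ps <- match_pac_spikes(pm, rwm)
  expect_equal(nrow(ps), 1L)                  # month 4 has zero mean rate
  expect_equal(ps$x, 0.03)
  expect_equal(ps$y, 0.2)
})

test_that("genotype contrasts: identical groups, variance gate, FDR power", {
  mm0 <- data.frame(subject_id = rep(paste0("m", 1:12), 2),
                    genotype = rep(c("WT", "APP"), each = 6),
                    age_month = rep(c(3, 4), each = 12),
                    value = rep(c(1, 1.1, 0.9, 1.05, 0.95, 1), 4))
  g0 <- genotype_compare(mm0, control = "WT")
  expect_equal(g0$delta, c(0, 0))
  expect_true(all(g0$p_raw > 0.99))
  expect_true(all(!g0$significant))
  expect_true(all(g0$test == ifelse(g0$levene_p < 0.05, "welch", "student")))
  # power at the reported effect scale: +0.2 shift, SD 0.1, n = 9/group,
  # embedded among 8 null months, flagged after BH-FDR
  set.seed(8)
  flags <- replicate(400, {
    months <- 3:11
    mk <- function(m) data.frame(
      subject_id = paste0(rep(c("w", "a"), each = 9), 1:9),
      genotype = rep(c("WT", "APP"), each = 9), age_month = m,
      value = c(rnorm(9, 1, 0.1), rnorm(9, 1 + if (m == 6) 0.2 else 0, 0.1)))
    g <- genotype_compare(do.call(rbind, lapply(months, mk)), control = "WT")
    g$significant[g$age_month == 6]
  })
  expect_gte(mean(flags), 0.8)
  # null cohort: family-wise false positives stay near the q level
  set.seed(9)
  fam <- replicate(200, {
    mk <- function(m) data.frame(
      subject_id = paste0(rep(c("w", "a"), each = 9), 1:9),
      genotype = rep(c("WT", "APP"), each = 9), age_month = m,
      value = rnorm(18, 1, 0.1))
    any(genotype_compare(do.call(rbind, lapply(3:11, mk)),
                         control = "WT")$significant)
  })
  expect_lte(mean(fam), 0.1)   # BH family error at q = 0.05, with slack
  # underfilled month skipped with a log note
  mm_small <- data.frame(subject_id = c("a", "b", "c"),
                         genotype = c("WT", "APP", "APP"),
                         age_month = 3, value = c(1, 2, 3))
  expect_equal(nrow(genotype_compare(mm_small)), 0L)
})

test_that("bmlm export writes the model-ready column contract", {
  em <- data.frame(subject_id = "m1", genotype = "WT", age_month = 3,
                   channel = "e1", metric = "fei", band_label = "b",
                   value = 1.02)
  f <- withr::local_tempfile(fileext = ".tsv")
  bmlm_export(em, f)
  out <- read.delim(f)
  expect_equal(names(out), c("value", "genotype", "age_month", "mouse", "channel"))
  expect_equal(out$value, 1.02)
})
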