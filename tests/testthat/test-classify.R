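# call-table constructors for rule-level tests (no rendering involved)
rise_at <- function(...) {
  pos <- c(numeric(0), ...)
  data.frame(position_bp = pos, sign = rep("rise", length(pos)),
             amplitude_pN = rep(5, length(pos)),
             width_bp = rep(5, length(pos)), start_bp = pos - 2,
             end_bp = pos + 2, stringsAsFactors = FALSE)
}
dip_at <- function(pos, start = pos - 6) {
  data.frame(position_bp = pos, sign = "dip", amplitude_pN = -3,
             width_bp = 10, start_bp = start, end_bp = pos + 4,
             stringsAsFactors = FALSE)
}

test_that("pre-chase classification follows the site-match rules", {
  con <- fixture_construct("PAM_proximal_first")   # dCas = clamp rise only
  clamp <- unzipr:::dcas_clamp_pos(con)            # 324
  cfg <- classifier_config()
  expect_equal(classify_prechase(rise_at(numeric(0)), con, cfg)$label, "Nak")
  expect_equal(classify_prechase(rise_at(50, clamp), con, cfg)$label,
               "A20_dCas")
  expect_equal(classify_prechase(rise_at(50), con, cfg)$label, "A20_only")
  expect_equal(classify_prechase(rise_at(clamp), con, cfg)$label,
               "dCas_only")
})

test_that("the 60-bp collision-competence boundary is applied strictly", {
  con <- fixture_construct("PAM_proximal_first")
  site <- unzipr:::dcas_site_ref(con)              # 333
  clamp <- unzipr:::dcas_clamp_pos(con)
  cfg <- classifier_config("RNAP")
  near <- classify_postchase(rise_at(site - 59, clamp), con, cfg)
  far <- classify_postchase(rise_at(site - 61, clamp), con, cfg)
  at_cut <- classify_postchase(rise_at(site - 60, clamp), con, cfg)
  expect_equal(near$label, "Coll")
  expect_equal(far$label, "TEC_up_dCas")
  expect_equal(at_cut$label, "Coll")               # <= cutoff collides
  # same distances without a dCas
  expect_equal(classify_postchase(rise_at(site - 59), con, cfg)$label,
               "dCas_rem")
  expect_equal(classify_postchase(rise_at(site - 61), con, cfg)$label,
               "TEC_up_only")
  # motor downstream without dCas
  expect_equal(classify_postchase(rise_at(site + 40), con, cfg)$label,
               "TEC_dn")
  expect_equal(classify_postchase(rise_at(numeric(0)), con, cfg)$label,
               "Nak")
  expect_equal(classify_postchase(rise_at(clamp), con, cfg)$label,
               "dCas_only")
})

test_that("distal-side dCas presence needs the dip or an upstream motor", {
  con <- fixture_construct("PAM_distal_first")
  clamp <- unzipr:::dcas_clamp_pos(con)            # 342
  rl <- unzipr:::rloop_window(con)
  cfg <- classifier_config()
  # dip + clamp rise: a bound dCas
  both <- rbind(dip_at(rl[1] + 5, start = rl[1] - 2), rise_at(clamp))
  expect_equal(classify_postchase(both, con, cfg)$label, "dCas_only")
  # lone rise in the footprint: an invading motor that removed the dCas
  expect_equal(classify_postchase(rise_at(rl[1] + 5), con, cfg)$label,
               "dCas_rem")
  # upstream motor rise + clamp rise, no dip: a collision
  expect_equal(classify_postchase(rise_at(rl[1] - 15, clamp), con,
                                  cfg)$label, "Coll")
})

test_that("Mfd uses the 70-bp cutoff", {
  con <- fixture_construct("PAM_proximal_first")
  site <- unzipr:::dcas_site_ref(con)
  clamp <- unzipr:::dcas_clamp_pos(con)
  cfg <- classifier_config("Mfd")
  expect_equal(cfg$cutoff_bp, 70)
  expect_equal(classify_postchase(rise_at(site - 65, clamp), con,
                                  cfg)$label, "Coll")
  expect_equal(classify_postchase(rise_at(site - 75, clamp), con,
                                  cfg)$label, "TEC_up_dCas")
})

test_that("batch classification conserves traces", {
  con <- fixture_construct("PAM_proximal_first")
  clamp <- unzipr:::dcas_clamp_pos(con)
  calls_list <- list(rise_at(50, clamp), rise_at(50), rise_at(numeric(0)),
                     rise_at(clamp))
  out <- classify_traces(calls_list, c("control", "control", "chase",
                                       "chase"), con)
  expect_equal(nrow(out), 4)
  expect_true(all(!is.na(out$category)))
  expect_equal(out$category, c("A20_dCas", "A20_only", "Nak", "dCas_only"))
})

test_that("invasion statistics match order-statistic oracles", {
  con <- fixture_construct("PAM_distal_first")
  rl <- unzipr:::rloop_window(con)
  # all peaks exactly at the R-loop edge: invasion 0, IQR width 0
  cl0 <- data.frame(category = "dCas_rem", motor_pos_bp = rep(rl[1], 5))
  s0 <- invasion_statistics(cl0, con)
  expect_equal(s0$p25, 0)
  expect_equal(s0$p75, 0)
  expect_equal(s0$sd, 0)
  # known positions: percentiles equal brute-force order statistics
  pos <- rl[1] + c(2, 5, 7, 11, 3, 8, 1)
  cl <- data.frame(category = "dCas_rem", motor_pos_bp = pos)
  s <- invasion_statistics(cl, con)
  inv <- sort(pos - rl[1])
  expect_equal(s$p25, unname(quantile(inv, 0.25)))
  expect_equal(s$p75, unname(quantile(inv, 0.75)))
  expect_equal(s$median, median(inv))
  expect_equal(s$n, 7)
  # deeper invasion settings move the median up (construction)
  shallow <- data.frame(category = "dCas_rem", motor_pos_bp = rl[1] + 1:5)
  deep <- data.frame(category = "dCas_rem", motor_pos_bp = rl[1] + 6:10)
  expect_lt(invasion_statistics(shallow, con)$median,
            invasion_statistics(deep, con)$median)
  # empty input gives an empty table, not an error
  expect_equal(nrow(invasion_statistics(
    data.frame(category = "Nak", motor_pos_bp = NA_real_), con)), 0)
})
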