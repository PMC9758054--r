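make_trace <- function(n = 100, rate = 10000) {
  unzip_trace(time = seq_len(n) / rate,
              force = sin(seq_len(n) / 5) + 10,
              extension = seq_len(n) * 0.05, rate_hz = rate)
}

test_that("decimation is exact block averaging", {
  tr <- make_trace(100)
  d <- decimate(tr, 1000)
  expect_equal(nrow(d), 10)
  # oracle: explicit block means
  expect_equal(d$force_pN,
               sapply(split(tr$force_pN, rep(1:10, each = 10)), mean),
               ignore_attr = TRUE)
  expect_equal(attr(d, "rate_hz"), 1000)
  # constant series unchanged
  cn <- unzip_trace(1:20, rep(5, 20), rep(7, 20), rate_hz = 10000)
  expect_true(all(decimate(cn, 1000)$force_pN == 5))
  # identity factor
  expect_identical(decimate(tr, 10000), tr)
  expect_error(decimate(tr, 3000), "integer factor")
})

test_that("bp conversion inverts the forward elastic model", {
  con <- fixture_construct()
  el <- elastic_params()
  f <- 14.2
  j <- c(5, 50, 200, 400)
  z <- con$arm_bp * dsdna_extension(f, el) + 2 * j * ssdna_extension(f, el)
  tr <- unzip_trace(seq_along(z), rep(f, length(z)), z)
  pt <- bp_from_force_extension(tr, el, con)
  expect_lt(max(abs(pt$bp_unzipped - j)), 0.1)
  # arms-only extension converts to j = 0
  tr0 <- unzip_trace(1, f, con$arm_bp * dsdna_extension(f, el))
  expect_lt(abs(bp_from_force_extension(tr0, el, con)$bp_unzipped), 1e-3)
  # monotone extension at fixed force gives monotone j
  zi <- seq(z[1], z[4], length.out = 50)
  ji <- bp_from_force_extension(
    unzip_trace(seq_along(zi), rep(f, 50), zi), el, con)$bp_unzipped
  expect_true(all(diff(ji) > 0))
  # sub-floor forces are masked, not converted
  trf <- unzip_trace(1:3, c(1, 2, 14.2), rep(z[2], 3))
  ptf <- bp_from_force_extension(trf, el, con)
  expect_equal(nrow(ptf), 1)
  expect_equal(attr(ptf, "n_masked"), 2)
})

test_that("alignment recovers a known shift and flags garbage", {
  con <- fixture_construct()
  th <- fixture_theory()
  # build a trace from the theory itself, shifted by +5 bp
  sub <- th[seq(1, nrow(th), by = 3), ]
  pt <- structure(
    data.frame(bp_unzipped = sub$bp_unzipped - 5,
               force_pN = sub$force_pN + rnorm(nrow(sub), 0, 0.1),
               extension_nm = sub$extension_nm),
    class = c("processed_trace", "data.frame"), aligned = FALSE)
  al <- withr::with_seed(1, align_to_theory(pt, th))
  expect_equal(attr(al, "offset_bp"), 5, tolerance = 0.5)
  expect_false(attr(al, "alignment_failed"))
  # already-aligned trace: identity within grid resolution
  pt0 <- structure(
    data.frame(bp_unzipped = sub$bp_unzipped, force_pN = sub$force_pN,
               extension_nm = sub$extension_nm),
    class = c("processed_trace", "data.frame"), aligned = FALSE)
  al0 <- align_to_theory(pt0, th)
  expect_equal(attr(al0, "offset_bp"), 0, tolerance = 0.26)
  expect_equal(attr(al0, "scale"), 1, tolerance = 0.0051)
  # pure noise cannot be aligned
  ptn <- structure(
    data.frame(bp_unzipped = sub$bp_unzipped,
               force_pN = withr::with_seed(2, rnorm(nrow(sub), 14, 3)),
               extension_nm = sub$extension_nm),
    class = c("processed_trace", "data.frame"), aligned = FALSE)
  expect_true(attr(align_to_theory(ptn, th), "alignment_failed"))
})

test_that("naked traces yield few false-positive calls", {
  con <- fixture_construct()
  th <- fixture_theory()
  n_fp <- withr::with_seed(31, sum(sapply(1:30, function(i) {
    tr <- render_trace("Nak", con)
    nrow(process_trace(tr, con, th)$calls) > 0
  })))
  expect_lte(n_fp, 3)   # < 5 percent per-trace rate, with binomial slack
})

test_that("a stalled-motor-plus-dCas trace shows the expected rises", {
  con <- fixture_construct("PAM_proximal_first")
  th <- fixture_theory("PAM_proximal_first")
  clamp <- unzipr:::dcas_clamp_pos(con)
  hits <- withr::with_seed(5, sapply(1:5, function(i) {
    tr <- render_trace("A20_dCas", con)
    calls <- process_trace(tr, con, th)$calls
    rises <- calls[calls$sign == "rise", ]
    nrow(rises) == 2 &&
      min(abs(rises$position_bp - 50)) <= 2 &&
      min(abs(rises$position_bp - clamp)) <= 2
  }))
  expect_gte(sum(hits), 4)
})

test_that("distal-side dCas traces show the breathing dip before the rise", {
  con <- fixture_construct("PAM_distal_first")
  th <- fixture_theory("PAM_distal_first")
  rl <- unzipr:::rloop_window(con)
  ok <- withr::with_seed(6, sapply(1:5, function(i) {
    calls <- process_trace(render_trace("dCas_only", con), con, th)$calls
    dips <- calls[calls$sign == "dip", ]
    rises <- calls[calls$sign == "rise", ]
    nrow(dips) >= 1 && nrow(rises) >= 1 &&
      dips$start_bp[1] < rises$start_bp[1] &&   # dip encountered first
      dips$start_bp[1] < rl[1]          # fork senses the bubble early
  }))
  expect_gte(sum(ok), 4)
})

test_that("transcript-annealing shortening corrects downstream calls", {
  # synthetic processed trace: fork advances, then a sustained 4-bp backward
  # jump at near-constant force, then advances again
  bp <- c(seq(0, 300, by = 0.5), seq(296, 400, by = 0.5))
  f <- rep(14, length(bp)) + rnorm(length(bp), 0, 0.05)
  pt <- structure(data.frame(bp_unzipped = bp, force_pN = f,
                             extension_nm = seq_along(bp)),
                  class = c("processed_trace", "data.frame"), aligned = TRUE)
  calls <- data.frame(position_bp = c(100, 340), sign = "rise",
                      amplitude_pN = 5, width_bp = 5,
                      start_bp = c(98, 338), end_bp = c(102, 342))
  cor <- withr::with_seed(3, correct_transcript_annealing(pt, calls))
  expect_equal(cor$position_bp[2], 344, tolerance = 1)
  expect_equal(cor$position_bp[1], 100)   # upstream call untouched
  expect_equal(attr(cor, "shortening_bp"), 4, tolerance = 1)
  # no shortening -> no-op
  pt2 <- structure(data.frame(bp_unzipped = seq(0, 400, by = 0.5),
                              force_pN = 14, extension_nm = 1:801),
                   class = c("processed_trace", "data.frame"),
                   aligned = TRUE)
  expect_equal(correct_transcript_annealing(pt2, calls)$position_bp,
               calls$position_bp)
  # shortening after the last call -> no change
  bp3 <- c(seq(0, 380, by = 0.5), seq(376, 400, by = 0.5))
  pt3 <- structure(data.frame(bp_unzipped = bp3, force_pN = 14,
                              extension_nm = seq_along(bp3)),
                   class = c("processed_trace", "data.frame"),
                   aligned = TRUE)
  calls3 <- calls[1, ]
  expect_equal(correct_transcript_annealing(pt3, calls3)$position_bp, 100)
})

test_that("calls are equivariant under a bp shift plus realignment", {
  con <- fixture_construct()
  th <- fixture_theory()
  tr <- withr::with_seed(8, render_trace("A20_dCas", con))
  pt <- bp_from_force_extension(tr, elastic_params(), con)
  calls1 <- call_interactions(align_to_theory(pt, th), th)
  pt2 <- pt
  pt2$bp_unzipped <- pt2$bp_unzipped - 7
  calls2 <- call_interactions(align_to_theory(pt2, th), th)
  expect_equal(calls1$position_bp, calls2$position_bp, tolerance = 0.6)
  expect_identical(calls1$sign, calls2$sign)
})

test_that("unaligned traces cannot be peak-called", {
  con <- fixture_construct()
  th <- fixture_theory()
  tr <- withr::with_seed(9, render_trace("Nak", con))
  pt <- bp_from_force_extension(tr, elastic_params(), con)
  expect_error(call_interactions(pt, th), "aligned")
})
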