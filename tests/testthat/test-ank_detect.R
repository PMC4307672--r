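# Rule-set criteria, boundary rules, greedy scan and tandem grouping.

test_that("detection_params validates its thresholds", {
  p <- detection_params()
  expect_equal(p$r_c, 7.0)
  expect_equal(c(p$peak_dist_min, p$peak_dist_max), c(5L, 15L))
  expect_error(detection_params(r_c = -1), "positive")
  expect_error(detection_params(peak_dist_min = 10, peak_dist_max = 5),
               "must not exceed")
})

test_that("find_hth_candidates pairs consecutive helices across TURN/COIL only", {
  seg <- seg_df(c("HELIX", "TURN", "HELIX", "STRAND", "HELIX", "COIL", "HELIX"),
                c(8L, 2L, 10L, 3L, 8L, 4L, 8L))
  levc <- rep(0.1, 43)
  levc[c(5, 15, 27, 40)] <- c(0.9, 0.8, 0.7, 0.6)
  cand <- find_hth_candidates(seg, fake_profile(levc))
  # helix2-helix3 blocked by the strand between them
  expect_equal(nrow(cand), 2L)
  expect_equal(cand$s1, c(1L, 24L))
  expect_equal(cand$e2, c(20L, 43L))
  expect_equal(cand$peak1, c(5L, 27L))
  expect_equal(cand$peak2, c(15L, 40L))
  none <- find_hth_candidates(seg_df("COIL", 10L), fake_profile(rep(0.3, 10)))
  expect_equal(nrow(none), 0L)
})

test_that("profile peaks break ties toward the lower index", {
  seg <- seg_df(c("HELIX", "TURN", "HELIX"), c(6L, 2L, 6L))
  cand <- find_hth_candidates(seg, fake_profile(rep(0.25, 14)))
  expect_equal(cand$peak1, 1L)
  expect_equal(cand$peak2, 9L)
})

test_that("anti-parallel criterion distinguishes helix orientations", {
  anti <- two_helix_pair(antiparallel = TRUE)
  para <- two_helix_pair(antiparallel = FALSE)
  # oracle: compare the two inter-helix distances directly
  d <- function(ch, i, j) sqrt(sum((ch$xyz[i, ] - ch$xyz[j, ])^2))
  expect_true(d(anti$chain, 1, 20) < d(anti$chain, 10, 20))
  expect_false(d(para$chain, 1, 20) < d(para$chain, 10, 20))
  expect_true(is_antiparallel(anti$chain, anti$pair))
  expect_false(is_antiparallel(para$chain, para$pair))
})

test_that("eigen dominance is strict", {
  pair <- data.frame(s1 = 1L, e1 = 4L, s2 = 6L, e2 = 9L)
  up <- fake_profile(c(0.4, 0.4, 0.4, 0.4, 0.1, 0.2, 0.2, 0.2, 0.2))
  eq <- fake_profile(rep(0.3, 9))
  expect_true(eigen_dominance(up, pair))
  expect_false(eigen_dominance(eq, pair))
  expect_false(eigen_dominance(fake_profile(rev(up$levc)), pair))
})

test_that("peak distance and core length are inclusive-bound checks", {
  mk <- function(p1, p2) data.frame(peak1 = p1, peak2 = p2)
  expect_true(peak_distance_ok(mk(10, 15)))    # distance 5
  expect_true(peak_distance_ok(mk(10, 25)))    # distance 15
  expect_false(peak_distance_ok(mk(10, 14)))   # 4
  expect_false(peak_distance_ok(mk(10, 26)))   # 16
  expect_false(peak_distance_ok(mk(25, 10)))   # signed: -15 fails
  core <- function(len) data.frame(s1 = 1L, e2 = len)
  expect_true(core_length_ok(core(13L)))
  expect_false(core_length_ok(core(12L)))
})

test_that("repeat start applies the -4 rule with chain-start clamping", {
  st <- repeat_start(data.frame(s1 = 10L))
  expect_equal(st$start, 6L)
  expect_false(st$terminal)
  st <- repeat_start(data.frame(s1 = 3L))
  expect_equal(st$start, 1L)
  expect_true(st$terminal)
  st <- repeat_start(data.frame(s1 = 5L))   # lands exactly on residue 1
  expect_equal(st$start, 1L)
  expect_false(st$terminal)
})

test_that("repeat end picks the lowest-profile turn residue in the window", {
  seg <- seg_df(c("HELIX", "TURN", "COIL"), c(20L, 5L, 15L))
  levc <- rep(0.5, 40)
  levc[21:25] <- c(0.30, 0.10, 0.05, 0.20, 0.40)
  pair <- data.frame(e2 = 20L)
  en <- repeat_end(fake_profile(levc), seg, pair)
  expect_equal(en$end, 23L)
  expect_equal(en$end_rule, "turn_min")
  # tie toward the lower index
  levc[21:25] <- c(0.1, 0.1, 0.1, 0.1, 0.1)
  expect_equal(repeat_end(fake_profile(levc), seg, pair)$end, 21L)
})

test_that("repeat end falls back to coil minima when the window has no turn", {
  seg <- seg_df(c("HELIX", "COIL"), c(20L, 20L))
  levc <- rep(0.5, 40)
  levc[28] <- 0.01
  en <- repeat_end(fake_profile(levc), seg, data.frame(e2 = 20L))
  expect_equal(en$end, 28L)
  expect_equal(en$end_rule, "turn_min")
})

test_that("repeat end window truncates at the next repeat and clips on collision", {
  seg <- seg_df(c("HELIX", "TURN", "COIL"), c(20L, 5L, 15L))
  levc <- rep(0.5, 40)
  levc[25] <- 0.01                        # global turn minimum at 25
  pair <- data.frame(e2 = 20L)
  # next repeat starts at 24: window stops at 23, minimum inside it
  levc[22] <- 0.10
  en <- repeat_end(fake_profile(levc), seg, pair, next_start = 24L)
  expect_equal(en$end, 22L)
  expect_equal(en$end_rule, "turn_min")
  # next repeat starts immediately after the second helix: clipped back
  en <- repeat_end(fake_profile(levc), seg, pair, next_start = 21L)
  expect_equal(en$end, 20L)
  expect_equal(en$end_rule, "clipped")
})

test_that("repeat end at the chain terminus uses the chain-end rule", {
  seg <- seg_df(c("COIL", "HELIX"), c(5L, 20L))
  en <- repeat_end(fake_profile(rep(0.5, 25)), seg, data.frame(e2 = 25L))
  expect_equal(en$end, 25L)
  expect_equal(en$end_rule, "chain_end")
  # window shorter than turn_window because the chain ends inside it
  seg <- seg_df(c("HELIX", "TURN"), c(20L, 5L))
  en <- repeat_end(fake_profile(rep(0.5, 25)), seg, data.frame(e2 = 20L))
  expect_equal(en$end_rule, "turn_min")    # turn present inside the window
  expect_equal(en$end, 21L)
})

test_that("full detection on a 3-copy fixture matches the construction", {
  spec <- ank_fixture_spec(3, seed = 1)
  ch <- build_ank_fixture(spec)
  seg <- assign_internal(ch)
  pr <- principal_eigenvector(build_contact_network(ch))
  res <- detect_ank(ch, seg, pr)
  expect_equal(nrow(res$repeats), 3L)
  expect_equal(nrow(res$regions), 1L)
  expect_equal(res$regions$n_repeats, 3L)
  # each detected first helix lies inside the constructed H1 of its copy
  copy_len <- spec$h1_len + spec$inner_turn_len + spec$h2_len + spec$loop_len
  for (k in 1:3) {
    h1_range <- (k - 1L) * copy_len + c(1L, spec$h1_len)
    expect_gte(res$repeats$s1[k], h1_range[1])
    expect_lte(res$repeats$e1[k], h1_range[2])
    h2_range <- (k - 1L) * copy_len + spec$h1_len + spec$inner_turn_len +
      c(1L, spec$h2_len)
    expect_gte(res$repeats$s2[k], h2_range[1])
    expect_lte(res$repeats$e2[k], h2_range[2])
  }
  expect_true(res$repeats$terminal[1])     # start clamped at residue 1
  expect_true(isTRUE(verify_detection(res, ch, seg, pr)))
})

test_that("detection is deterministic", {
  ch <- build_ank_fixture(ank_fixture_spec(4, seed = 6))
  seg <- assign_internal(ch)
  pr <- principal_eigenvector(build_contact_network(ch))
  expect_identical(detect_ank(ch, seg, pr), detect_ank(ch, seg, pr))
})

test_that("single repeats and far-apart repeats are never reported", {
  # one copy: a lone motif is not a tandem region
  ch1 <- build_ank_fixture(ank_fixture_spec(1, seed = 1))
  res1 <- detect_ank(ch1, assign_internal(ch1),
                     principal_eigenvector(build_contact_network(ch1)))
  expect_equal(nrow(res1$repeats), 0L)
  expect_equal(nrow(res1$regions), 0L)
  # two copies separated by a 25-residue loop: gap exceeds the tandem limit
  ch2 <- build_ank_fixture(ank_fixture_spec(2, loop_len = 25L, seed = 1))
  res2 <- detect_ank(ch2, assign_internal(ch2),
                     principal_eigenvector(build_contact_network(ch2)))
  expect_equal(nrow(res2$regions), 0L)
})

test_that("negative controls: single helix and parallel bundle", {
  hel <- chain_structure(build_helix(helix_spec(60)))
  res <- detect_ank(hel, assign_internal(hel),
                    principal_eigenvector(build_contact_network(hel)))
  expect_equal(nrow(res$repeats), 0L)
  bundle <- parallel_bundle_chain()
  seg <- assign_internal(bundle)
  pr <- principal_eigenvector(build_contact_network(bundle))
  cand <- find_hth_candidates(seg, pr)
  expect_gte(nrow(cand), 1L)               # the pair exists ...
  expect_false(is_antiparallel(bundle, cand[1, ]))  # ... and fails criterion i
  expect_equal(nrow(detect_ank(bundle, seg, pr)$repeats), 0L)
})

test_that("accepted repeats never share a helix", {
  ch <- build_ank_fixture(ank_fixture_spec(5, seed = 8))
  seg <- assign_internal(ch)
  pr <- principal_eigenvector(build_contact_network(ch))
  res <- detect_ank(ch, seg, pr)
  expect_equal(nrow(res$repeats), 5L)
  for (k in seq_len(nrow(res$repeats) - 1L))
    expect_gt(res$repeats$s1[k + 1L], res$repeats$e2[k])
  expect_true(isTRUE(verify_detection(res, ch, seg, pr)))
})

test_that("batch filter drops short fragments only", {
  expect_false(chain_passes_batch_filter(collinear_chain(49, 3.8)))
  expect_true(chain_passes_batch_filter(collinear_chain(50, 3.8)))
})
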