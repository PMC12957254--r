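test_that("build_contingency matches hand enumeration and the brute-force oracle", {
  rec <- data.table::data.table(
    primaryid = c("r1", "r1", "r2", "r2"),
    drug = c("X", "X", "Y", "Y"),
    pt = c("p1", "p2", "p1", "p2"))
  tab <- build_contingency(rec, "X", "p1")
  expect_equal(unlist(tab[c("a", "b", "c", "d")]),
               c(a = 1L, b = 1L, c = 1L, d = 1L))
  # absent PT -> a = 0, c = 0
  tab0 <- build_contingency(rec, "X", "nope")
  expect_equal(tab0$a, 0L)
  expect_equal(tab0$c, 0L)
  # absent drug -> flagged
  expect_false(build_contingency(rec, "Z", "p1")$drug_present)

  # exhaustive recount on synthetic records
  env <- shared_synth()
  recs <- env$records
  set.seed(99)
  some_pts <- sample(unique(recs$pt), 8L)
  for (pt in some_pts) {
    got <- build_contingency(recs, "risankizumab", pt)
    want <- brute_contingency(recs, "risankizumab", pt)
    expect_equal(unlist(got[c("a", "b", "c", "d")]), want, label = pt)
  }
})

test_that("disproportionality_stats matches closed forms", {
  # perfect independence
  s1 <- disproportionality_stats(1, 1, 1, 1)
  expect_equal(s1$ror, 1)
  expect_equal(s1$prr, 1)
  expect_equal(s1$chisq, 0)
  expect_equal(s1$ic, 0)
  # direct formula evaluation
  s2 <- disproportionality_stats(20, 10, 10, 20)
  expect_equal(s2$ror, 4)
  expect_equal(s2$prr, 2)
  expect_equal(s2$chisq, 60 * (20 * 20 - 10 * 10)^2 / (30 * 30 * 30 * 30))
  expect_equal(s2$ic, log2(4 / 3))
  expect_equal(s2$ic025, log2(4 / 3) - 3.3 / sqrt(20) - 2 * 20^-1.5)
  expect_equal(s2$ror_lo,
               exp(log(4) - 1.96 * sqrt(1 / 20 + 1 / 10 + 1 / 10 + 1 / 20)))
  expect_equal(s2$prr_lo,
               exp(log(2) - 1.96 * sqrt(1 / 20 - 1 / 30 + 1 / 10 - 1 / 30)))
  # CI brackets the point estimate
  expect_true(s2$ror_lo <= s2$ror && s2$ror <= s2$ror_hi)
})

test_that("zero cells are flagged, never infinite", {
  s <- disproportionality_stats(0, 10, 5, 100)
  expect_true(is.na(s$ror) && is.na(s$ic))
  s2 <- disproportionality_stats(5, 0, 5, 100)
  expect_true(is.na(s2$ror))
  expect_false(is.na(s2$prr))  # PRR defined with b = 0
  expect_false(any(vapply(disproportionality_stats(3, 0, 0, 0),
                          function(x) any(is.infinite(x)), logical(1))))
  # Haldane correction makes them finite
  sh <- disproportionality_stats(5, 0, 5, 100, haldane = TRUE)
  expect_false(is.na(sh$ror))
})

test_that("independence null and monotonicity invariants hold", {
  set.seed(7)
  for (i in 1:20) {
    a <- sample(1:50, 1); k <- sample(1:5, 1); m <- sample(1:5, 1)
    # ad = bc by construction
    s <- disproportionality_stats(a, a * k, a * m, a * k * m)
    expect_equal(s$ror, 1)
    expect_equal(s$prr, 1)
    expect_equal(s$chisq, 0)
    expect_equal(s$ic, 0)
  }
  # increasing a with margins fixed increases ROR, PRR, IC
  n_drug <- 100; n_evt <- 80; N <- 1000
  a <- 5:40
  s <- disproportionality_stats(a, n_drug - a, n_evt - a,
                                N - n_drug - n_evt + a)
  expect_true(all(diff(s$ror) > 0))
  expect_true(all(diff(s$prr) > 0))
  expect_true(all(diff(s$ic) > 0))
  # IC - IC025 shrinks as a grows
  expect_true(all(diff(s$ic - s$ic025) < 0))
  # ror >= prr when prr > 1
  big <- s[s$prr > 1]
  expect_true(all(big$ror >= big$prr))
})

test_that("large-margin tables give ROR ~ PRR within 1%", {
  s <- disproportionality_stats(50, 20000, 400, 900000)
  expect_lt(abs(s$ror - s$prr) / s$prr, 0.01)
})

test_that("evaluate_signal applies the three-rule criteria", {
  crit <- signal_criteria()
  # n = 2 never fires regardless of strength
  s <- disproportionality_stats(2, 1, 1, 1000)
  expect_false(evaluate_signal(s, crit)$signal)
  # PRR thresholds are inclusive: PRR = 2, chisq = 4 fires
  fake <- data.table::data.table(n = 3, ror = 1.5, ror_lo = 0.9,
                                 ror_hi = 2, prr = 2, prr_lo = 1,
                                 prr_hi = 4, chisq = 4, ic = 0.5,
                                 ic025 = -0.1)
  ev <- evaluate_signal(fake, crit)
  expect_true(ev$sig_prr)
  expect_true(ev$signal)
  # all rules failing -> negative
  fake2 <- data.table::data.table(n = 5, ror = 1.2, ror_lo = 0.9,
                                  ror_hi = 1.6, prr = 1.5, prr_lo = 1,
                                  prr_hi = 2, chisq = 3, ic = 0.1,
                                  ic025 = -0.1)
  expect_false(evaluate_signal(fake2, crit)$signal)
  # combine = "all" is stricter than "any"
  strict <- signal_criteria(combine = "all")
  ev3 <- evaluate_signal(fake, strict)
  expect_false(ev3$signal)
})

test_that("screen_all_pts ranks injected pairs first and honors exclusions", {
  env <- shared_synth()
  recs <- env$records
  scr <- screen_all_pts(recs, "risankizumab")
  expect_equal(scr$pt[1], "pt_30")   # injected RR = 10
  expect_true(scr$signal[1])
  # stats columns agree with a one-off build_contingency on the same pair
  tab <- build_contingency(recs, "risankizumab", "pt_30")
  one <- disproportionality_stats(tab)
  expect_equal(scr$ror[1], one$ror)
  expect_equal(scr$chisq[scr$pt == "pt_30"], one$chisq)
  # excluded PT never appears regardless of strength
  scr2 <- screen_all_pts(recs, "risankizumab", exclusions = "pt_30")
  expect_false("pt_30" %in% scr2$pt)
  # min_n filter: all PTs below threshold -> empty result
  few <- data.table::data.table(primaryid = c("1", "2"),
                                drug = c("X", "Y"), pt = c("p", "p"))
  expect_equal(nrow(screen_all_pts(few, "X", signal_criteria(min_n = 3))), 0L)
  # raising min_n yields a subset
  scr10 <- screen_all_pts(recs, "risankizumab",
                          criteria = signal_criteria(min_n = 10L))
  expect_true(all(scr10$pt %in% scr$pt))
  expect_true(all(scr10$n >= 10))
})

test_that("soc_profile proportions are normalized per drug", {
  rec <- data.table::data.table(
    primaryid = as.character(1:100),
    drug = "risankizumab",
    pt = rep(c("p1", "p2"), c(30, 70)),
    is_target = TRUE)
  map <- data.table::data.table(pt = c("p1", "p2"),
                                soc = c("soc_a", "soc_b"))
  prof <- soc_profile(rec, map)
  expect_equal(prof$prop[prof$soc == "soc_a"], 0.30)
  expect_equal(prof$prop[prof$soc == "soc_b"], 0.70)
  expect_equal(sum(prof$prop), 1)
  # unmapped PTs bucketed with a warning
  expect_warning(prof2 <- soc_profile(rec, map[1]), "unmapped")
  expect_equal(sum(prof2$prop), 1)
  # shared synthetic records: proportions sum to 1 per drug
  env <- shared_synth()
  vocab <- env$gen$manifest$pt_vocab
  map_all <- data.table::data.table(
    pt = vocab$pt, soc = rep(c("soc_a", "soc_b", "soc_c"),
                             length.out = nrow(vocab)))
  prof3 <- soc_profile(env$records, map_all)
  sums <- tapply(prof3$prop, prof3$drug, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("soc_bubble_table recomputes plot coordinates from stats", {
  env <- shared_synth()
  scr <- screen_all_pts(env$records, "guselkumab")
  map <- data.table::data.table(pt = scr$pt, soc = "soc_x")
  bub <- soc_bubble_table(scr, map)
  expect_equal(bub$log2_ror, log2(scr$ror))
  expect_equal(bub$sqrt_chisq, sqrt(scr$chisq))
  expect_equal(bub$n, scr$n)
})

test_that("reconstruct_contingency inverts printed PRR/chisq", {
  # synthetic truth: build a table, print its stats, reconstruct
  a <- 500; b <- 9500; cc <- 2000; d <- 188000
  s <- disproportionality_stats(a, b, cc, d)
  rec <- reconstruct_contingency(a, a + b, s$prr, s$chisq)
  expect_equal(rec$c, cc, tolerance = 1e-6)
  expect_equal(rec$d, d, tolerance = 1e-6)
  expect_equal(rec$ror, s$ror, tolerance = 1e-10)
})
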