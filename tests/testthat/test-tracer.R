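test_that("labeled fractions follow the [labeled]/[total] definition", {
  tab <- isotopologue_table(
    data.frame(metabolite = rep(c("pyr", "cit"), c(4, 3)),
               mass_shift = c(0, 1, 2, 3, 0, 2, 3),
               sample = "s1",
               area = c(50, 25, 25, 0, 900, 100, 0)),
    n_carbons = c(pyr = 3, cit = 6))
  expect_equal(unname(labeled_fraction(tab, "cit", 2, by_group = FALSE)$per_sample),
               0.100)
  expect_equal(unname(labeled_fraction(tab, "pyr", 2, by_group = FALSE)$per_sample),
               0.25)
  # all area at M0: any k > 0 has fraction 0
  expect_equal(unname(labeled_fraction(tab, "cit", 3, by_group = FALSE)$per_sample),
               0)
  expect_equal(unname(labeled_fraction(tab, "cit", 0, by_group = FALSE)$per_sample),
               0.9)

  # zero total area flags the sample
  z <- isotopologue_table(
    data.frame(metabolite = "x", mass_shift = c(0, 1), sample = "s1",
               area = c(0, 0)), n_carbons = c(x = 2))
  rec <- labeled_fraction(z, "x", 1, by_group = FALSE)
  expect_true(is.na(rec$per_sample))
  expect_equal(rec$flagged_samples, "s1")

  # group means average per-sample fractions
  gt <- isotopologue_table(
    data.frame(metabolite = "x", mass_shift = rep(c(0, 1), 2),
               sample = rep(c("w1", "w2"), each = 2),
               area = c(90, 10, 70, 30)),
    n_carbons = c(x = 2), groups = c(w1 = "W", w2 = "W"))
  expect_equal(unname(labeled_fraction(gt, "x", 1)$group_mean), 0.2)
})

test_that("natural-abundance correction inverts the forward binomial convolution", {
  # unlabeled 2-carbon metabolite observed with natural 13C only
  obs <- natural_abundance_convolve(
    isotopologue_vector("x", 2, c(1, 0, 0)), p13 = 0.011)
  expect_equal(unname(obs$fractions),
               c((1 - 0.011)^2, 2 * 0.011 * (1 - 0.011), 0.011^2),
               tolerance = 1e-12)
  corr <- natural_abundance_correct(obs, p13 = 0.011)
  expect_equal(unname(corr$fractions), c(1, 0, 0), tolerance = 1e-9)

  # round trip on arbitrary vectors recovers the input within 1e-6
  set.seed(2)
  for (i in 1:10) {
    n <- sample(2:7, 1)
    f <- runif(n + 1); f <- f / sum(f)
    v <- isotopologue_vector("m", n, f)
    back <- natural_abundance_correct(natural_abundance_convolve(v, 0.0107),
                                      p13 = 0.0107)
    expect_lt(max(abs(back$fractions - v$fractions)), 1e-6)
  }

  # fully labeled input is a fixed point; disabled correction is identity
  full <- isotopologue_vector("m", 3, c(0, 0, 0, 1))
  expect_equal(natural_abundance_correct(
    natural_abundance_convolve(full))$fractions, full$fractions,
    tolerance = 1e-9)
  expect_identical(natural_abundance_correct(full, enabled = FALSE), full)
  expect_error(natural_abundance_correct(full, p13 = 0.2), "parameter error")
})

test_that("network construction validates fractions and honors toggles", {
  expect_error(build_network(f_ppp = 1.2), "parameter error")
  expect_error(build_network(f_lactate = 0.6, f_pdh = 0.6),
               "sum to <= 1")
  expect_error(build_network(dilution = c(NOPE = 0.1)), "unknown")
  expect_error(build_network(f_shuttle = 0.5, shuttle = FALSE),
               "shuttle disabled")

  net <- build_network()
  aud <- audit_network(net)
  # oxidative PPP: Ru5P takes G6P carbons 2-6, carbon 1 leaves as CO2
  ox <- Filter(function(r) r$name == "oxidative_ppp", net$routes)[[1]]
  expect_equal(ox$map[, 2], 2:6)
  expect_equal(unname(ox$co2[1, ]), c(1L, 1L))
  # citrate synthase: every citrate carbon traces to AcCoA or OAA
  cs <- Filter(function(r) r$name == "citrate_synthase", net$routes)[[1]]
  expect_setequal(cs$substrates[cs$map[, 1]], c(rep("OAA", 4), rep("AcCoA", 2)))
  # disabling the shuttle removes only cytosolic pools
  off <- build_network(f_shuttle = 0, shuttle = FALSE)
  gone <- setdiff(names(net$n_carbons), names(off$n_carbons))
  expect_setequal(gone, c("CIT_cyt", "AcCoA_cyt", "OAA_cyt", "MAL_cyt"))
})

test_that("per-route carbon accounting balances product, CO2 and co-product", {
  net <- build_network(f_pc = 0.1)
  aud <- audit_network(net)
  # single-product reactions: substrate carbons all reach the product or a
  # designated CO2 loss (the CO2-fixing carboxylase carbon is an entry, so
  # it still balances)
  multi <- c("aldolase", "transketolase1", "transketolase2", "transaldolase",
             "atp_citrate_lyase")
  for (i in seq_len(nrow(aud))) {
    r <- aud[i, ]
    if (r$reaction %in% multi) next
    expect_equal(r$carbons_in, r$carbons_to_product + r$carbons_to_co2,
                 info = r$reaction)
  }
  # multi-product reactions: the sibling products jointly carry every
  # substrate carbon of the full reaction
  full_in <- c(aldolase = 6, transketolase1 = 10, transketolase2 = 9,
               transaldolase = 10, atp_citrate_lyase = 6)
  for (rx in multi) {
    rows <- aud[aud$reaction == rx, ]
    expect_equal(sum(rows$carbons_to_product), unname(full_in[rx]),
                 info = rx)
  }
})

test_that("tracer limits: no label, pure glycolysis, PPP ribose, citrate M2", {
  # no tracer: every pool is M0
  s0 <- simulate_isotopomers(build_network(tracer_purity = 0))
  expect_true(all(vapply(s0, function(v) abs(v$fractions[["M0"]] - 1) < 1e-9,
                         logical(1))))
  # pure glycolysis at full purity: PYR, LAC, PEP are 100% M3
  s1 <- simulate_isotopomers(build_network(f_ppp = 0, f_shuttle = 0,
                                           f_lactate = 1, f_pdh = 0,
                                           tracer_purity = 1))
  for (m in c("PYR", "LAC", "PEP"))
    expect_equal(unname(s1[[m]]$fractions[["M3"]]), 1, tolerance = 1e-9)
  # fully labeled G6P carbons 2-6: R5P is 100% M5
  expect_equal(unname(s1$R5P$fractions[["M5"]]), 1, tolerance = 1e-9)
  # first-turn citrate with unlabeled oxaloacetate carries the two acetyl
  # carbons: 100% M2
  s2 <- simulate_isotopomers(build_network(f_ppp = 0, f_shuttle = 0,
                                           tracer_purity = 1,
                                           dilution = c(OAA = 1)))
  expect_equal(unname(s2$CIT$fractions[["M2"]]), 1, tolerance = 1e-9)

  # all fraction vectors sum to 1 everywhere
  sim <- simulate_isotopomers(build_network(f_ppp = 0.2, f_shuttle = 0.5,
                                            tracer_purity = 0.95,
                                            dilution = c(OAA = 0.2)))
  expect_true(all(vapply(sim, function(v) abs(sum(v$fractions) - 1) < 1e-9,
                         logical(1))))
})

test_that("succinate scrambling makes its positional distribution palindromic", {
  sim <- simulate_isotopomers(build_network(f_ppp = 0.1, f_shuttle = 0.3,
                                            tracer_purity = 0.9))
  pos <- attr(sim, "positional")$SUC
  # reversal permutation on 4 carbons
  rev_idx <- vapply(0:15, function(s) {
    bits <- as.integer(intToBits(s))[1:4]
    sum(rev(bits) * 2^(0:3))
  }, numeric(1)) + 1
  expect_equal(pos, pos[rev_idx], tolerance = 1e-9)
})

test_that("PYR M3 enrichment is monotone in tracer purity", {
  purities <- seq(0, 1, by = 0.2)
  m3 <- vapply(purities, function(p) {
    sim <- simulate_isotopomers(build_network(f_ppp = 0.1, f_shuttle = 0.3,
                                              tracer_purity = p))
    unname(sim$PYR$fractions[["M3"]])
  }, numeric(1))
  expect_true(all(diff(m3) >= -1e-12))
  expect_equal(m3[1], 0, tolerance = 1e-9)
})

test_that("solver and Monte-Carlo oracle agree molecule for distribution", {
  net <- build_network(f_ppp = 0.15, f_shuttle = 0.4, tracer_purity = 0.95,
                       dilution = c(OAA = 0.25, AKG = 0.2))
  det <- simulate_isotopomers(net)
  n <- 2e4
  mc <- monte_carlo_oracle(net, n_molecules = n, seed = 42)
  dev <- max(vapply(names(det), function(m)
    max(abs(det[[m]]$fractions - mc[[m]]$fractions)), numeric(1)))
  expect_lt(dev, 3 / sqrt(n))
  # oracle is seed-deterministic
  mc2 <- monte_carlo_oracle(net, n_molecules = 5e3, seed = 7, n_iter = 10,
                            n_tally = 5)
  mc3 <- monte_carlo_oracle(net, n_molecules = 5e3, seed = 7, n_iter = 10,
                            n_tally = 5)
  expect_identical(lapply(mc2, `[[`, "fractions"),
                   lapply(mc3, `[[`, "fractions"))
})

test_that("non-convergence is reported with the residual", {
  net <- build_network()
  expect_error(simulate_isotopomers(net, tolerance = 1e-12, max_iter = 2L),
               "did not converge")
})
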