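test_that("transfer frequency is transconjugants per donor", {
  a <- data.frame(donor_cfu_per_ml = 1e7, transconjugant_cfu_per_ml = 1e4)
  expect_equal(transferFrequency(a)$per_replicate, 1e-3)
  a0 <- data.frame(donor_cfu_per_ml = 1e7, transconjugant_cfu_per_ml = 0)
  expect_equal(transferFrequency(a0)$per_replicate, 0)
  expect_error(transferFrequency(
    data.frame(donor_cfu_per_ml = 0, transconjugant_cfu_per_ml = 1)),
    "undefined")
  # scale invariance to a common volume factor
  a3 <- data.frame(donor_cfu_per_ml = c(2e7, 5e6, 9e6),
                   transconjugant_cfu_per_ml = c(3e4, 8e3, 2e4))
  a3x <- a3 * 17
  expect_equal(transferFrequency(a3)$per_replicate,
               transferFrequency(a3x)$per_replicate)
  expect_equal(transferFrequency(a3)$n, 3)
})

test_that("fold change reports ratio and direction", {
  expect_equal(foldChange(1e-3, 1e-3)$ratio, 1)
  fc <- foldChange(5e-3, 2.5e-6)
  expect_equal(fc$ratio, 2000)       # the reported 2e3-fold descriptor
  expect_equal(fc$direction, "higher")
  lo <- foldChange(2.5e-6, 5e-3)
  expect_equal(lo$fold, 2000)
  expect_equal(lo$direction, "lower")
  expect_error(foldChange(1, 0), "> 0")
})

test_that("survival rate is the selective/non-selective CFU percentage", {
  expect_equal(survivalRate(1e9, 1e9)$per_replicate, 100)
  expect_equal(survivalRate(0, 1e9)$per_replicate, 0)
  expect_error(survivalRate(1, 0), "undefined")
  r <- survivalRate(c(3e6, 4e6, 2e6), c(1e9, 1e9, 1e9))
  expect_equal(r$mean, mean(c(0.3, 0.4, 0.2)))
  # common dilution factor cancels
  expect_equal(survivalRate(c(3e6, 4e6) * 10, c(1e9, 1e9) * 10)$per_replicate,
               survivalRate(c(3e6, 4e6), c(1e9, 1e9))$per_replicate)
})

test_that("equal-variance t test matches the closed-form oracle", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  r <- tTestEqualVar(a, b)
  expect_equal(r$p_value, oracleTTest(a, b), tolerance = 1e-12)
  expect_equal(r$df, 4)
  # and stats::t.test as a second, independent route
  expect_equal(r$p_value, t.test(a, b, var.equal = TRUE)$p.value,
               tolerance = 1e-10)
  # random inputs, both routes, 1e-10 agreement
  for (i in 1:20) {
    x <- withSeed(i, list(a = rnorm(3 + i %% 4, 0, 1 + i %% 3),
                          b = rnorm(3 + (i + 1) %% 5, i %% 2, 2)))
    r <- tTestEqualVar(x$a, x$b)
    expect_equal(r$p_value, t.test(x$a, x$b, var.equal = TRUE)$p.value,
                 tolerance = 1e-10)
    expect_equal(r$p_value, oracleTTest(x$a, x$b), tolerance = 1e-10)
  }
  # degenerate input
  expect_equal(tTestEqualVar(c(2, 2, 2), c(2, 2))$p_value, 1)
  expect_error(tTestEqualVar(c(2, 2, 2), c(3, 3)), "degenerate")
  expect_error(tTestEqualVar(1, c(2, 3)), "at least 2")
})

test_that("significance pattern of triplicate contrasts at published scales", {
  # synthetic triplicates at the reported group means/sds: the survival
  # contrast (0.3 +/- 0.3 vs 100 +/- 12) is overwhelming, the generation-time
  # contrast (74.4 +/- 6.8 vs 68.2 +/- 8.1) is not
  surv <- withSeed(21, list(wt = rnorm(3, 100, 12), mut = rnorm(3, 0.3, 0.3)))
  expect_lt(tTestEqualVar(surv$wt, surv$mut)$p_value, 0.001)
  gt <- withSeed(22, list(wt = rnorm(3, 74.4, 6.8), mut = rnorm(3, 68.2, 8.1)))
  expect_gt(tTestEqualVar(gt$wt, gt$mut)$p_value, 0.05)
})

test_that("Tukey letters collapse and separate in the forced cases", {
  same <- withSeed(31, lapply(setNames(1:4, paste0("g", 1:4)),
                              function(i) rnorm(3, 0, 1)))
  gc <- anovaTukey(same)
  expect_true(all(lettersTable(gc)$letters == "a"))
  two <- withSeed(32, list(lo = rnorm(3, 0, 0.1), hi = rnorm(3, 10, 0.1)))
  gc2 <- anovaTukey(two)
  lt <- lettersTable(gc2)
  expect_setequal(lt$letters, c("a", "b"))
  expect_equal(lt$group[lt$letters == "a"], "hi")  # 'a' labels the top mean
  expect_error(anovaTukey(list(a = 1:3)), "at least 2")
  expect_error(anovaTukey(list(a = 1:3, b = numeric(0))), "at least 2")
})

test_that("letter partitions match the brute-force pairwise oracle", {
  for (i in 1:25) {
    g <- withSeed(400 + i, {
      mu <- sample(c(0, 0.5, 1, 1.5, 3, 6), 4)
      setNames(lapply(mu, function(m) rnorm(3, m, 1)), paste0("g", 1:4))
    })
    gc <- anovaTukey(g, alpha = 0.05)
    nsd <- oracleTukeyNsd(g, alpha = 0.05)
    expect_true(lettersAgree(gc, nsd))
    # adjusted p values agree with TukeyHSD (equal n: Tukey-Kramer = Tukey)
    labs <- names(g)
    x <- unlist(g); grp <- factor(rep(labs, lengths(g)), levels = labs)
    tk <- stats::TukeyHSD(stats::aov(x ~ grp))$grp
    for (r in seq_len(nrow(gc@pairwise))) {
      key <- paste0(gc@pairwise$group2[r], "-", gc@pairwise$group1[r])
      expect_equal(gc@pairwise$p_adj[r], tk[key, "p adj"], tolerance = 1e-8)
    }
  }
})

test_that("letter partition is invariant to group input order", {
  g <- withSeed(55, list(a = rnorm(3, 0), b = rnorm(3, 1), c = rnorm(3, 6),
                         d = rnorm(3, 6.2)))
  lt1 <- lettersTable(anovaTukey(g))
  lt2 <- lettersTable(anovaTukey(g[c(3, 1, 4, 2)]))
  lt2 <- lt2[match(lt1$group, lt2$group), ]
  expect_equal(lt1$letters, lt2$letters)
})

test_that("log10 transform handles zeros through the pseudo-frequency floor", {
  g <- list(wt = c(1e-3, 2e-3, 1.5e-3), mut = c(0, 1e-7, 2e-7))
  expect_error(anovaTukey(g, log10_transform = TRUE), "pseudo_floor")
  expect_message(
    gc <- anovaTukey(g, log10_transform = TRUE, pseudo_floor = 5e-8),
    "pseudo_floor")
  expect_s4_class(gc, "GroupComparison")
  expect_true(gc@log10_transformed)
})
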