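test_that("fractionation factors are exact differences with their symmetries", {
  expect_equal(epsilon_a(-140, -50), -90)
  expect_equal(epsilon_a(-50, -50), 0)
  expect_equal(epsilon_h(-50, -120), 70)
  expect_equal(epsilon_h(-180, -120), -60)
  # epsilon_a(delta, w) + w = delta; antisymmetry; chain additivity
  d <- c(-203, -161.8, -73.5, 0, 25)
  w <- -45.2
  expect_equal(epsilon_a(d, w) + w, d)
  expect_equal(epsilon_h(d, rev(d)), -epsilon_h(rev(d), d))
  expect_equal(epsilon_h(d[1], d[3]),
               epsilon_h(d[1], d[2]) + epsilon_h(d[2], d[3]))
  # ratio-based form differs from the difference form except at equality
  expect_equal(epsilon_ratio(-100, -100), 0)
  expect_gt(abs(epsilon_ratio(-50, -120) - epsilon_h(-50, -120)), 1)
})

test_that("weighted alkane mean renormalizes, bounds and rejects bad profiles", {
  expect_equal(weighted_alkane_mean(data.frame(abundance = 1, delta2H = -152)),
               -152)
  expect_equal(weighted_alkane_mean(data.frame(abundance = c(0.5, 0.5),
                                               delta2H = c(-150, -170))),
               -160)
  prof <- data.frame(abundance = c(0.1, 0.4, 0.4, 0.1),
                     delta2H = c(-160, -150, -140, -130))
  expect_equal(weighted_alkane_mean(prof), -145)
  # permutation invariance and min/max bounds
  perm <- prof[c(3, 1, 4, 2), ]
  expect_equal(weighted_alkane_mean(perm), weighted_alkane_mean(prof))
  expect_gte(weighted_alkane_mean(prof), min(prof$delta2H))
  expect_lte(weighted_alkane_mean(prof), max(prof$delta2H))
  # slight mis-normalization tolerated and renormalized exactly
  prof2 <- prof
  prof2$abundance <- prof2$abundance * 1.01
  expect_equal(weighted_alkane_mean(prof2), -145)
  prof2$abundance <- prof2$abundance * 1.05
  expect_error(weighted_alkane_mean(prof2), "outside")
  prof$abundance[1] <- -0.1
  expect_error(weighted_alkane_mean(prof), "negative")
})

test_that("tissue offsets pair replicates within treatment and average treatments equally", {
  s <- generate_n_experiment(synthetic_config(noise_sd = 0))
  off <- tissue_offset(s, "water", "leaf", "root")
  expect_equal(as.numeric(off), 29.6)
  expect_equal(as.numeric(tissue_offset(s, "sugars", "root", "leaf")), 17.3)
  by_tr <- attr(off, "by_treatment")
  expect_equal(nrow(by_tr), 7)
  expect_true(all(by_tr$n_pairs == 5))
  # truncated replicates pair on the shared indices only
  expect_equal(as.numeric(tissue_offset(s, "cellulose", "root", "leaf")), 12.3)
  expect_error(tissue_offset(s, "alkane_C29", "leaf", "root"), "root")
})

test_that("fractionation table covers the named contrasts and tolerates absences", {
  s <- generate_n_experiment(synthetic_config(noise_sd = 0))
  ft <- fractionation_table(s)
  ea <- ft[ft$kind == "epsilon_a", ]
  eh <- ft[ft$kind == "epsilon_h", ]
  # every alkane chain sits at the configured autotrophic fractionation
  expect_equal(unique(ea$value[grepl("alkane", ea$compound_a)]), -128.8)
  # heterotrophic contrasts exist in all three tissue contexts
  expect_setequal(unique(eh$context), c("L", "R", "R-L"))
  # contrast chain: eps_h(C,St) = eps_h(C,S) + eps_h(S,St) within any cell
  pick <- function(a, b, ctx) {
    v <- eh$value[eh$compound_a == a & eh$compound_b == b &
                    eh$context == ctx & eh$treatment == 50 &
                    eh$replicate == 1]
    v[1]
  }
  expect_equal(pick("cellulose", "starch", "L"),
               pick("cellulose", "sugars", "L") - pick("starch", "sugars", "L"))
  # root-leaf starch contrast carries the configured tissue offset at zero noise
  st_rl <- eh$value[eh$compound_a == "starch" & eh$context == "R-L" &
                      eh$compound_b == "sugars"]
  expect_true(all(is.finite(st_rl)))

  # dataset with only water yields an empty table, not an error
  expect_equal(nrow(fractionation_table(s[s$compound == "water", ])), 0)
})
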