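design <- make_sample_design(tissues = "liver")
screen <- build_screen_design(design)

test_that("factor incidence is derived from the group composition", {
  eff <- screen$comparison[screen$effective]
  expect_setequal(eff, c("TC-LC", "TC-LTC", "HLC-LC", "HLC-LTC"))
  expect_setequal(screen$comparison[!screen$effective],
                  c("TC-HLC", "LTC-LC"))
  fac <- setNames(screen$factors, screen$comparison)
  expect_equal(fac[["TC-HLC"]], "BR,EE")
  expect_equal(fac[["TC-LC"]], "BR,EN,EE")
  expect_equal(fac[["TC-LTC"]], "EN,EE")
  expect_error(build_screen_design(design[design$group != "LC", ]),
               "four")
})

test_that("the liver worked example yields exactly its three candidates", {
  ms <- dem_membership_example("liver")
  cand <- screen_enm(ms, screen)
  expect_setequal(cand$feature, c("miR-10c-5p", "miR-144-5p", "miR-144-3p"))
  pref <- setNames(cand$altitude_preference, cand$feature)
  expect_equal(pref[["miR-10c-5p"]], "LOW")
  expect_equal(pref[["miR-144-5p"]], "HIGH")
  expect_equal(pref[["miR-144-3p"]], "HIGH")
  expect_equal(length(intersect_effective(ms, screen)), 9)
})

test_that("the other tissue worked examples reproduce their counts", {
  expect_equal(length(intersect_effective(dem_membership_example("lung"),
                                          screen)), 6)
  expect_equal(length(intersect_effective(dem_membership_example("heart"),
                                          screen)), 2)
  heart <- screen_enm(dem_membership_example("heart"), screen)
  expect_equal(heart$feature, "miR-3536")
  brain <- screen_enm(dem_membership_example("brain"), screen)
  expect_equal(nrow(brain), 0)
})

test_that("empty DE sets produce no candidates", {
  empty <- setNames(
    rep(list(data.frame(feature = character(), direction = character())), 6),
    screen$comparison)
  expect_equal(nrow(screen_enm(empty, screen)), 0)
  expect_equal(length(intersect_effective(empty, screen)), 0)
})

test_that("the screen equals a brute-force set-algebra oracle on random fixtures", {
  set.seed(303)
  feats <- sprintf("m%02d", 1:50)
  for (rep in 1:5) {
    de_sets <- setNames(lapply(screen$comparison, function(cmp) {
      chosen <- feats[runif(50) < 0.4]
      data.frame(feature = chosen,
                 direction = sample(c("UP_IN_A", "UP_IN_B"),
                                    length(chosen), replace = TRUE),
                 stringsAsFactors = FALSE)
    }), screen$comparison)
    eff <- screen$comparison[screen$effective]
    ineff <- screen$comparison[!screen$effective]
    oracle <- Filter(function(f) {
      all(vapply(eff, function(c) f %in% de_sets[[c]]$feature, logical(1))) &&
        !any(vapply(ineff, function(c) f %in% de_sets[[c]]$feature,
                    logical(1)))
    }, feats)
    expect_setequal(screen_enm(de_sets, screen)$feature, oracle)
    # intersection equals a fold-left pairwise intersection
    fold <- Reduce(intersect,
                   lapply(de_sets[eff], function(d) d$feature))
    expect_setequal(intersect_effective(de_sets, screen), fold)
  }
})

test_that("results are invariant to comparison orientation", {
  ms <- dem_membership_example("liver")
  flipped <- ms
  flip <- function(nm) paste(rev(strsplit(nm, "-")[[1]]), collapse = "-")
  names(flipped) <- vapply(names(ms), flip, character(1))
  for (i in seq_along(flipped)) {
    d <- flipped[[i]]
    d$direction <- ifelse(d$direction == "UP_IN_A", "UP_IN_B", "UP_IN_A")
    flipped[[i]] <- d
  }
  a <- screen_enm(ms, screen)
  b <- screen_enm(flipped, screen)
  expect_equal(a[order(a$feature), ], b[order(b$feature), ],
               ignore_attr = TRUE)
})

test_that("missing comparisons and directions are hard errors", {
  ms <- dem_membership_example("liver")
  expect_error(screen_enm(ms[-1], screen), "missing comparisons")
  broken <- ms
  broken[["TC-LC"]]$direction[broken[["TC-LC"]]$feature == "miR-10c-5p"] <-
    NA_character_
  expect_error(screen_enm(broken, screen), "missing direction")
})

test_that("membership tables cover every comparison", {
  ms <- dem_membership_example("lung")
  mt <- membership_table(ms, screen)
  expect_setequal(setdiff(names(mt), "feature"), screen$comparison)
  expect_true(all(mt$feature[rowSums(mt[, screen$comparison[screen$effective]]) == 4] %in%
                    intersect_effective(ms, screen)))
})
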