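test_that("frequency counts stores, not within-recipe quantity", {
  ds <- toy_survey()  # {A,B}, {A,C}, {A}
  f <- material_frequencies(ds)
  expect_equal(f$counts, c(A = 3L, B = 1L, C = 1L))
  expect_equal(f$N, 3)
  expect_equal(f$total_occurrences, 5)
})

test_that("registry materials used nowhere keep count zero", {
  attrs <- make_attrs(c("A", "B", "X"))
  ds <- make_dataset(list(s1 = c("A", "B"), s2 = "A"), attrs = attrs)
  f <- material_frequencies(ds)
  expect_equal(f$counts[["X"]], 0L)
  # and a zero-count material leaves Shannon unchanged
  ds0 <- make_dataset(list(s1 = c("A", "B"), s2 = "A"))
  expect_equal(shannon_diversity(f),
               shannon_diversity(material_frequencies(ds0)))
})

test_that("use values are count/N and display at the conventional 3 decimals", {
  f <- structure(list(counts = c(ap = 10L, an = 9L, ia = 8L, z = 0L, all = 32L),
                      N = 32L, total_occurrences = 59L),
                 class = "frequency_table")
  uv <- use_values(f)
  expect_identical(uv[["ap"]], 10 / 32)   # 0.3125 exactly
  expect_identical(uv[["z"]], 0)
  expect_identical(uv[["all"]], 1)
  expect_equal(display_uv(uv[["ap"]]), 0.312)  # tie rounds to even
  expect_equal(display_uv(uv[["an"]]), 0.281)
  expect_equal(display_uv(uv[["ia"]]), 0.25)
})

test_that("use values error when no formulation exists", {
  f <- structure(list(counts = c(a = 0L), N = 0L, total_occurrences = 0L),
                 class = "frequency_table")
  expect_error(use_values(f), "N >= 1")
})

test_that("Shannon index matches closed forms and an independent oracle", {
  equal4 <- structure(list(counts = c(a = 3L, b = 3L, c = 3L, d = 3L),
                           N = 12L, total_occurrences = 12L),
                      class = "frequency_table")
  expect_equal(shannon_diversity(equal4), 2)          # log2(4)
  single <- structure(list(counts = c(a = 7L), N = 7L, total_occurrences = 7L),
                      class = "frequency_table")
  expect_equal(shannon_diversity(single), 0)

  # worked contribution: count 10 out of 183 total occurrences
  p <- 10 / 183
  expect_equal(-p * log2(p), 0.2291679, tolerance = 1e-6)

  skip_if_not_installed("vegan")
  set.seed(11)
  for (i in 1:10) {
    counts <- rpois(15, 4) + 1L
    names(counts) <- paste0("m", 1:15)
    f <- structure(list(counts = counts, N = 30L,
                        total_occurrences = sum(counts)),
                   class = "frequency_table")
    expect_equal(shannon_diversity(f),
                 vegan::diversity(counts, index = "shannon", base = 2))
  }
})

test_that("Shannon properties: bounds, permutation invariance, uniform maximum", {
  set.seed(42)
  for (i in 1:20) {
    s <- sample(2:12, 1)
    counts <- stats::setNames(sample(1:9, s, replace = TRUE), paste0("m", 1:s))
    f <- structure(list(counts = counts, N = 20L,
                        total_occurrences = sum(counts)),
                   class = "frequency_table")
    h <- shannon_diversity(f)
    expect_gte(h, 0)
    expect_lte(h, log2(s) + 1e-12)
    perm <- sample(counts)
    fp <- structure(list(counts = perm, N = 20L,
                         total_occurrences = sum(perm)),
                    class = "frequency_table")
    expect_equal(shannon_diversity(fp), h)
    if (length(unique(counts)) == 1) expect_equal(h, log2(s))
  }
})

test_that("abundance vector sums to one with strictly positive entries", {
  set.seed(5)
  for (i in 1:10) {
    counts <- stats::setNames(c(rpois(8, 3), 0L), paste0("m", 1:9))
    f <- structure(list(counts = counts, N = 10L,
                        total_occurrences = sum(counts)),
                   class = "frequency_table")
    if (sum(counts) == 0) next
    p <- abundance_vector(f)
    expect_equal(sum(p), 1, tolerance = 1e-9)
    expect_true(all(unclass(p) > 0))
  }
  empty <- structure(list(counts = c(a = 0L), N = 2L, total_occurrences = 0L),
                     class = "frequency_table")
  expect_error(abundance_vector(empty), "zero")
})

test_that("mean formulation size is total occurrences over N", {
  ds <- make_dataset(list(s1 = c("A", "B"), s2 = "A"))
  expect_equal(mean_formulation_size(ds), 1.5)
  ones <- make_dataset(list(s1 = "A", s2 = "B", s3 = "C"))
  expect_equal(mean_formulation_size(ones), 1)
  # exact integer identity before rounding
  ds2 <- generate_survey(generator_config(n_stores = 15, n_species = 25,
                                          mean_size = 4), seed = 3)
  expect_equal(mean_formulation_size(ds2) * ds2$N,
               sum(lengths(ds2$formulations$materials)))
  # 183 occurrences over 32 formulations displays as 5.7
  expect_equal(round(183 / 32, 1), 5.7)
})

test_that("family shares count species once even when split into two materials", {
  attrs <- make_attrs(c("t1", "t2", "a1", "b1"),
                      scientific_name = c("Tithonia diversifolia",
                                          "Tithonia diversifolia",
                                          "Andrographis paniculata",
                                          "Ajuga nipponensis"),
                      family = c("Asteraceae", "Asteraceae", "Acanthaceae",
                                 "Lamiaceae"))
  attrs$part_used <- c("stem", "leaf", "whole_plant", "whole_plant")
  ds <- make_dataset(list(s1 = c("t1", "a1"), s2 = c("t2", "b1")),
                     attrs = attrs)
  fd <- family_distribution(ds)
  ast <- fd[fd$family == "Asteraceae", ]
  expect_equal(ast$n_species, 1L)          # one species, two materials
  expect_equal(ast$species_share, 1 / 3)
  expect_equal(ast$formulation_share, 1)   # in both formulations
  # the printed-style share: 12 species of 72 shows as 16.7%
  expect_equal(display_pct(12 / 72), 16.7)
})

test_that("part distribution sums to one and blank parts fall under 'other'", {
  attrs <- make_attrs(c("A", "B", "C"), part_used = c("whole_plant", "leaf", ""))
  ds <- make_dataset(list(s1 = c("A", "B", "C")), attrs = attrs)
  pd <- part_distribution(ds)
  expect_equal(sum(pd), 1)
  expect_equal(pd[["other"]], 1 / 3)
  expect_equal(display_pct(30 / 73), 41.1) # printed convention check
})

test_that("source shares count flags independently and 'both' separately", {
  attrs <- make_attrs(paste0("m", 1:10))
  attrs$cultivated <- rep(c(TRUE, FALSE), c(6, 4))
  attrs$wild <- c(rep(TRUE, 4), FALSE, FALSE, rep(TRUE, 3), FALSE)
  ds <- make_dataset(list(s1 = paste0("m", 1:10)), attrs = attrs)
  sd_ <- source_distribution(ds)
  expect_equal(sd_$cultivated_share, 0.6)
  expect_equal(sd_$wild_share, 0.7)
  expect_equal(sd_$both_share, 0.4)
})

test_that("property shares exclude unannotated materials from the denominator", {
  props <- c(rep("cold", 33), rep("cool", 19), rep("neutral", 10),
             rep("warm", 6), rep("hot", 3), rep("unknown", 2))
  attrs <- make_attrs(sprintf("m%02d", seq_along(props)), property = props)
  ds <- make_dataset(list(s1 = attrs$material_id), attrs = attrs)
  pf <- property_flavor_crosstab(ds)
  expect_equal(pf$n_annotated, 71L)
  expect_equal(pf$property_shares[["cold"]], 33 / 71)
  expect_equal(display_pct(pf$property_shares[["cold"]]), 46.5)
  expect_equal(sum(pf$property_shares), 1)
})

test_that("flavor shares use multi-membership and the joint table is consistent", {
  attrs <- make_attrs(c("A", "B"), property = c("cold", "cool"),
                      flavors = c("bitter;sweet", "bitter"))
  ds <- make_dataset(list(s1 = c("A", "B")), attrs = attrs)
  pf <- property_flavor_crosstab(ds)
  expect_equal(pf$flavor_shares[["bitter"]], 1)
  expect_equal(pf$flavor_shares[["sweet"]], 0.5)
  expect_equal(pf$joint_shares["cold", "bitter"], 0.5)
  expect_equal(pf$joint_shares["cold", "salty"], 0)
  # single annotated cold+bitter material -> joint share 1
  one <- make_dataset(list(s1 = "A"),
                      attrs = make_attrs("A", property = "cold",
                                         flavors = "bitter"))
  expect_equal(property_flavor_crosstab(one)$joint_shares["cold", "bitter"], 1)
  # all-unknown datasets warn and return empty shares
  unk <- make_dataset(list(s1 = "A"),
                      attrs = make_attrs("A", property = "unknown"))
  expect_warning(pfu <- property_flavor_crosstab(unk), "no materials")
  expect_length(pfu$property_shares, 0)
})

test_that("tag prevalence counts carriers over the chosen denominator", {
  tags <- c(rep("heat-clearing;detoxification", 4),
            rep("heat-clearing", 6), rep("", 6))
  attrs <- make_attrs(sprintf("m%02d", 1:16), function_tags = tags)
  ds <- make_dataset(list(s1 = attrs$material_id), attrs = attrs)
  tp <- tag_prevalence(ds, "function_tags")
  expect_equal(tp[["heat-clearing"]], 10 / 16)
  expect_equal(tp[["detoxification"]], 4 / 16)
  tp2 <- tag_prevalence(ds, "function_tags", denominator = "tagged")
  expect_equal(tp2[["heat-clearing"]], 1)
  expect_error(tag_prevalence(ds, "colour_tags"))
})

test_that("UV is monotone in count at fixed N and bounded in [0,1]", {
  for (N in c(5L, 32L)) {
    counts <- stats::setNames(0:N, paste0("m", 0:N))
    f <- structure(list(counts = counts, N = N, total_occurrences = sum(counts)),
                   class = "frequency_table")
    uv <- use_values(f)
    expect_true(all(uv >= 0 & uv <= 1))
    expect_true(all(diff(uv[order(counts)]) >= 0))
  }
})
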