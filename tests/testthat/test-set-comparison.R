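test_that("regional subsets keep only their region's formulations and materials", {
  ds <- make_dataset(list(s1 = c("A", "B"), s2 = c("C"), s3 = c("A")),
                     regions = c("north", "south", "north"))
  subs <- regional_subsets(ds)
  expect_named(subs, c("north", "south"))
  expect_equal(subs$north$N, 2)
  expect_setequal(subs$north$materials$material_id, c("A", "B"))
  expect_setequal(subs$south$materials$material_id, "C")
  # the subsets partition the formulations
  expect_equal(sum(vapply(subs, function(d) d$N, integer(1))), ds$N)
})

test_that("per-region species counts match brute-force set unions", {
  ds <- generate_survey(generator_config(n_stores = 40, n_species = 30,
                                         mean_size = 4), seed = 9)
  subs <- regional_subsets(ds)
  for (r in names(subs)) {
    sel <- ds$formulations$region == r
    brute <- unique(unlist(ds$formulations$materials[sel]))
    f <- material_frequencies(subs[[r]])
    expect_setequal(names(f$counts)[f$counts > 0], brute)
    expect_equal(sum(f$counts > 0), length(brute))
  }
})

test_that("shared materials across regions is the exact intersection", {
  common <- paste0("c", 1:9)
  sets <- list(n1 = c(common, "x1", "x2"), c1 = c(common, "y1"),
               s1 = c(common, "z1", "z2", "z3"))
  ds <- make_dataset(sets, regions = c("north", "central", "south"))
  subs <- regional_subsets(ds)
  expect_setequal(shared_materials(subs), common)
  # identical regions share everything; disjoint regions share nothing
  same <- make_dataset(list(a = c("A", "B"), b = c("A", "B")),
                       regions = c("north", "south"))
  expect_setequal(shared_materials(regional_subsets(same)), c("A", "B"))
  disj <- make_dataset(list(a = "A", b = "B"), regions = c("north", "south"))
  expect_length(shared_materials(regional_subsets(disj)), 0)
})

test_that("venn signature counts match per-element brute-force classification", {
  set.seed(21)
  for (trial in 1:15) {
    k <- sample(2:4, 1)
    universe <- paste0("e", 1:20)
    invs <- stats::setNames(
      lapply(seq_len(k), function(i) sample(universe, sample(0:15, 1))),
      paste0("inv", seq_len(k)))
    vp <- venn_partition(invs)
    oracle <- oracle_venn_counts(invs)
    for (s in names(vp$counts)) {
      expected <- if (s %in% names(oracle)) as.integer(oracle[[s]]) else 0L
      expect_equal(unname(vp$counts[[s]]), expected, info = s)
    }
    expect_equal(sum(vp$counts), vp$union_size)
    sizes <- vapply(invs, function(x) length(unique(x)), integer(1))
    expect_equal(unname(vp$set_sizes), unname(sizes))
  }
})

test_that("venn partition is invariant to inventory order up to relabeling", {
  invs <- list(a = c("x", "y", "z"), b = c("y", "w"), c = c("z", "w", "v"))
  vp1 <- venn_partition(invs)
  vp2 <- venn_partition(invs[c("c", "a", "b")])
  expect_equal(vp1$union_size, vp2$union_size)
  expect_equal(sort(unname(vp1$counts)), sort(unname(vp2$counts)))
  expect_equal(vp1$exclusive_counts[["a"]], vp2$exclusive_counts[["a"]])
})

test_that("two identical sets put all mass on signature 11", {
  vp <- venn_partition(list(a = c("x", "y"), b = c("y", "x")))
  expect_equal(unname(vp$counts[["11"]]), 2L)
  expect_equal(unname(vp$counts[["10"]]), 0L)
  expect_equal(unname(vp$counts[["01"]]), 0L)
  # empty inventories are allowed
  vp0 <- venn_partition(list(a = c("x"), b = character(0)))
  expect_equal(unname(vp0$counts[["10"]]), 1L)
  expect_equal(vp0$union_size, 1L)
})

test_that("exclusivity percentages match the survey-comparison conventions", {
  # 35 materials of a 73-material inventory found nowhere else
  own <- paste0("m", 1:73)
  other <- c(paste0("m", 36:73), paste0("o", 1:10))
  vp <- venn_partition(list(taiwan = own, mainland = other))
  expect_equal(unname(vp$exclusive_counts[["taiwan"]]), 35L)
  expect_equal(round(100 * vp$exclusive_shares[["taiwan"]]), 48)
  # 11 of 73 shared across all four inventories
  shared <- paste0("m", 1:11)
  four <- list(taiwan = own,
               lingnan = c(shared, paste0("l", 1:20)),
               chaoshan = c(shared, paste0("c", 1:15)),
               fujian = c(shared, paste0("f", 1:12)))
  vp4 <- venn_partition(four)
  expect_equal(unname(vp4$counts[["1111"]]), 11L)
  expect_equal(display_pct(vp4$counts[["1111"]] / length(own)), 15.1)
})

test_that("scientific-name normalisation strips authorities and annotations", {
  expect_equal(normalize_scientific_name("Ixeris chinensis (Thunb. ex Thunb.) Nakai"),
               "ixeris chinensis")
  expect_equal(normalize_scientific_name("Tithonia diversifolia (stem)"),
               "tithonia diversifolia")
  expect_equal(normalize_scientific_name("Andrographis  paniculata (Burm. f.) Nees"),
               "andrographis paniculata")
  expect_equal(normalize_scientific_name(c("A b C", "X y")), c("a b", "x y"))
})

test_that("top-k overlap takes the k highest-UV materials with stable ties", {
  uv_a <- stats::setNames(c(0.5, 0.4, 0.3, 0.3, 0.1), paste0("m", 1:5))
  uv_b <- stats::setNames(c(0.6, 0.4, 0.2), c("m1", "x1", "x2"))
  vp <- top_k_overlap(uv_a, uv_b, k = 3, labels = c("a", "b"))
  expect_equal(unname(vp$counts[["11"]]), 1L)  # only m1 shared
  # identical tables overlap fully
  vp2 <- top_k_overlap(uv_a, uv_a, k = 4)
  expect_equal(unname(vp2$counts[["11"]]), 4L)
  # disjoint tables overlap nowhere
  uv_c <- stats::setNames(c(0.9, 0.8), c("z1", "z2"))
  vp3 <- top_k_overlap(uv_a, uv_c, k = 2)
  expect_equal(unname(vp3$counts[["11"]]), 0L)
  # requesting more than available warns (once per inventory) and uses all
  expect_warning(expect_warning(top_k_overlap(uv_c, uv_c, k = 5), "only 2"),
                 "only 2")
})

test_that("a planted 4-member overlap among two top-15 lists is recovered", {
  shared <- paste0("s", 1:4)
  a_only <- paste0("a", 1:11)
  b_only <- paste0("b", 1:11)
  uv_a <- stats::setNames(seq(0.9, 0.2, length.out = 15), c(shared, a_only))
  uv_b <- stats::setNames(seq(0.9, 0.2, length.out = 15), c(shared, b_only))
  # bury the shared names under extra low-UV tail entries
  uv_a <- c(uv_a, stats::setNames(rep(0.05, 5), paste0("ta", 1:5)))
  uv_b <- c(uv_b, stats::setNames(rep(0.05, 5), paste0("tb", 1:5)))
  vp <- top_k_overlap(uv_a, uv_b, k = 15, labels = c("bt", "qcc"))
  expect_equal(unname(vp$counts[["11"]]), 4L)
})
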