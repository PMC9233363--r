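test_that("methylation_level implements 100 * numC / (numC + numT)", {
  expect_equal(methylation_level(30, 70), 30)
  expect_equal(methylation_level(0, 50), 0)
  expect_equal(methylation_level(2, 98), 2)
  expect_equal(methylation_level(c(1, 3), c(3, 1)), c(25, 75))
  expect_error(methylation_level(0, 0), "Zero coverage")
  expect_error(methylation_level(-1, 5), "nonnegative")
})

test_that("filter_by_coverage keeps exactly the calls at or above the cutoff", {
  calls <- tibble::tibble(
    position = 1:4, strand = "+",
    count_methylated = c(0, 10, 15, 1),
    count_unmethylated = c(29, 20, 15, 0)
  )
  kept <- filter_by_coverage(calls, 30)
  expect_equal(kept$position, c(2, 3))  # 29 dropped, 30 kept
  expect_equal(nrow(filter_by_coverage(calls, 1)), 4)
  expect_error(filter_by_coverage(calls, 0), ">= 1")
})

test_that("filter_by_coverage matches a linear-scan oracle on random data", {
  set.seed(77)
  calls <- tibble::tibble(
    position = 1:500, strand = "+",
    count_methylated = rpois(500, 3),
    count_unmethylated = rpois(500, 40)
  )
  for (mc in c(1, 10, 30, 60)) {
    keep <- logical(500)
    for (i in 1:500) {
      keep[i] <- calls$count_methylated[i] + calls$count_unmethylated[i] >= mc
    }
    expect_equal(filter_by_coverage(calls, mc)$position, calls$position[keep])
  }
})

test_that("build_matrix enforces the detectable-in-all-samples rule", {
  mk <- function(id, cov) {
    tibble::tibble(individual_id = id, area = "NAcc",
                   position = 1:3, strand = "+",
                   context = "CHH", trinucleotide = "CTT",
                   count_methylated = 1L, count_unmethylated = cov - 1L)
  }
  calls <- dplyr::bind_rows(mk("a", c(50L, 50L, 50L)),
                            mk("b", c(50L, 29L, 50L)),
                            mk("c", c(50L, 50L, 50L)))
  mat <- build_matrix(calls, 30)
  expect_equal(mat$sites$position, c(1, 3))  # site 2 fails in sample b
  expect_false(anyNA(mat$levels))
  # identical samples retain everything
  calls2 <- dplyr::bind_rows(mk("a", c(40L, 40L, 40L)), mk("b", c(40L, 40L, 40L)))
  expect_equal(nrow(build_matrix(calls2, 30)$sites), 3)
  # duplicated site within one sample is an error
  expect_error(build_matrix(dplyr::bind_rows(mk("a", c(50L, 50L, 50L)),
                                             mk("a", c(50L, 50L, 50L)),
                                             mk("b", c(50L, 50L, 50L))), 30),
               "Duplicate")
})

test_that("build_matrix is permutation-invariant and monotone in min_coverage", {
  sim <- small_dataset()
  calls <- sim$calls[sim$calls$area == "NAcc", ]
  mat <- build_matrix(calls, 30)
  shuffled <- calls[rev(seq_len(nrow(calls))), ]
  mat2 <- build_matrix(shuffled, 30)
  expect_equal(mat$sites, mat2$sites)
  ord <- match(mat$samples$sample_id, mat2$samples$sample_id)
  expect_equal(mat$levels, mat2$levels[, ord, drop = FALSE])
  # raising the cutoff never adds a site
  for (mc in c(40, 60, 90)) {
    stricter <- build_matrix(calls, mc)
    expect_true(all(paste(stricter$sites$position, stricter$sites$strand) %in%
                      paste(mat$sites$position, mat$sites$strand)))
  }
})

test_that("lower NAcc coverage yields fewer NAcc sites than PFC sites", {
  cfg <- small_config(genome_length = 2000L, seed = 13L)
  sim <- simulate_dataset(cfg)
  nacc <- sim$calls[sim$calls$area == "NAcc", ]
  # halve NAcc coverage to emulate fewer reads from that area
  nacc$count_unmethylated <- nacc$count_unmethylated %/% 2L
  nacc$count_methylated <- nacc$count_methylated %/% 2L
  pfc <- sim$calls[sim$calls$area == "PFC", ]
  expect_lt(nrow(build_matrix(nacc, 30)$sites),
            nrow(build_matrix(pfc, 30)$sites))
})

test_that("overlap_sites equals the set-intersection oracle", {
  sim <- small_dataset()
  mat_a <- build_matrix(sim$calls, 30, area = "NAcc")
  mat_b <- build_matrix(sim$calls, 30, area = "PFC")
  shared <- overlap_sites(mat_a, mat_b)
  oracle <- intersect(paste(mat_a$sites$position, mat_a$sites$strand),
                      paste(mat_b$sites$position, mat_b$sites$strand))
  expect_setequal(paste(shared$position, shared$strand), oracle)
  expect_equal(overlap_sites(mat_a, mat_a)$position, mat_a$sites$position)
  # disjoint site sets give an empty overlap
  mat_c <- mat_b
  mat_c$sites$position <- mat_c$sites$position + 100000L
  expect_equal(nrow(overlap_sites(mat_a, mat_c)), 0)
})

test_that("tidy() and subset_matrix() agree with the grids", {
  sim <- small_dataset()
  mat <- build_matrix(sim$calls, 30, area = "NAcc")
  long <- tidy(mat)
  expect_equal(nrow(long), nrow(mat$sites) * nrow(mat$samples))
  i <- 3L
  j <- 2L
  row <- long[long$position == mat$sites$position[i] &
                long$strand == mat$sites$strand[i] &
                long$sample_id == mat$samples$sample_id[j], ]
  expect_equal(row$level, unname(mat$levels[i, j]))
  cpg <- subset_matrix(mat, context_subset = "CpG_only")
  expect_true(all(cpg$sites$context == "CpG"))
  two <- subset_matrix(mat, individual_ids = mat$samples$individual_id[1:2])
  expect_equal(ncol(two$levels), 2)
})
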