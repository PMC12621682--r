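test_that("encode_pairs writes one-hot constraints with mirrors", {
  tn <- encode_pairs(2, paired = rbind(c(0, 1)))
  expect_equal(tn$A[1, 2, ], c(0L, 0L, 1L))
  expect_equal(tn$A[2, 1, ], c(0L, 0L, 1L))
  expect_equal(tn$A[1, 1, ], c(1L, 0L, 0L))
  expect_equal(tn$A[2, 2, ], c(1L, 0L, 0L))

  tn <- encode_pairs(3)
  expect_true(all(tn$A[, , 1] == 1L))

  tn <- encode_pairs(3, nonpaired = rbind(c(0, 2)))
  ch <- tn$A[, , 2]
  expect_equal(sum(ch), 2L)                 # the cell and its mirror
  expect_equal(sum(tn$A[, , 1]), 7L)        # everything else unspecified
  expect_no_error(validate_tensor(tn))
})

test_that("conflicting cell assignments error instead of overwriting", {
  expect_error(encode_pairs(4, paired = rbind(c(0, 1)), nonpaired = rbind(c(1, 0))),
               class = "natk_conflict")
  tn <- encode_pairs(8, nonpaired = rbind(c(0, 7)))
  expect_error(encode_region_pair(tn, region_pair(c(0, 3), c(5, 8))),
               class = "natk_conflict")
  expect_error(encode_pairs(4, paired = rbind(c(0, 0))), class = "natk_invalid")
  expect_error(encode_pairs(4, paired = rbind(c(0, 4))), class = "natk_invalid")
})

test_that("region pairs land on the anti-diagonal or diagonal", {
  tn <- encode_region_pair(conditioning_tensor(8),
                           region_pair(c(0, 3), c(5, 8), "antiparallel"))
  expect_true(pairs_equal(decode_tensor(tn)$paired,
                          rbind(c(0, 7), c(1, 6), c(2, 5))))
  # paired cells of the region submatrix sit exactly on the anti-diagonal
  sub <- tn$A[1:3, 6:8, 3]
  expect_equal(sub != 0L, diag(3)[, 3:1] != 0)

  tn <- encode_region_pair(conditioning_tensor(8),
                           region_pair(c(0, 3), c(5, 8), "parallel"))
  expect_true(pairs_equal(decode_tensor(tn)$paired,
                          rbind(c(0, 5), c(1, 6), c(2, 7))))
  expect_equal(tn$A[1:3, 6:8, 3] != 0L, diag(3) != 0)

  # width-1 regions: orientation is degenerate
  for (ori in c("antiparallel", "parallel")) {
    tn <- encode_region_pair(conditioning_tensor(4),
                             region_pair(c(0, 1), c(3, 4), ori))
    expect_true(pairs_equal(decode_tensor(tn)$paired, rbind(c(0, 3))))
  }

  expect_error(region_pair(c(0, 3), c(4, 6)), class = "natk_shape")
  expect_error(region_pair(c(0, 4), c(2, 6)), class = "natk_overlap")
})

test_that("region-pair encoding is mirror-symmetric and idempotent", {
  for (ori in c("antiparallel", "parallel")) {
    rp_ab <- region_pair(c(1, 4), c(6, 9), ori)
    rp_ba <- region_pair(c(6, 9), c(1, 4), ori)
    a <- encode_region_pair(conditioning_tensor(10), rp_ab)
    b <- encode_region_pair(conditioning_tensor(10), rp_ba)
    expect_equal(a$A, b$A)
    twice <- encode_region_pair(a, rp_ab)
    expect_equal(twice$A, a$A)
  }
})

test_that("tensor invariants hold after randomized operations", {
  for (seed in 1:10) {
    set.seed(seed)
    L <- sample(6:20, 1)
    ss <- random_ss(L, seed + 100)
    tn <- from_secondary_structure(ss, unpaired_as_nonpairing = (seed %% 2 == 0))
    expect_no_error(validate_tensor(tn))
    sets <- decode_tensor(tn)
    back <- encode_pairs(L, sets$paired, sets$nonpaired)
    expect_equal(back$A, tn$A)   # encode(decode(A)) == A
    expect_true(pairs_equal(sets$paired, ss$pairs) || nrow(ss$pairs) == 0)
  }
})

test_that("secondary-structure conversion honors the loop-enforcement flag", {
  ss <- parse_dotbracket("((..))")
  tn <- from_secondary_structure(ss, FALSE)
  expect_equal(sum(tn$A[, , 3]) / 2L, 2L)
  expect_equal(sum(tn$A[, , 2]), 0L)

  tn <- from_secondary_structure(ss, TRUE)
  sets <- decode_tensor(tn)
  expect_true(pairs_equal(sets$nonpaired, rbind(c(2, 3))))

  tn <- from_secondary_structure(parse_dotbracket("..."), TRUE)
  expect_true(all(tn$A[, , 2][upper.tri(diag(3))] == 1L))
})

test_that("multi-partner accumulation is kept and exports fail loudly", {
  tn <- conditioning_tensor(9)
  tn <- encode_region_pair(tn, region_pair(c(0, 2), c(4, 6), "parallel"))
  tn <- encode_region_pair(tn, region_pair(c(4, 6), c(7, 9), "parallel"))
  sets <- decode_tensor(tn)
  # base 4 is paired with 0 and with 7
  partners <- c(sets$paired[sets$paired[, 1] == 4, 2],
                sets$paired[sets$paired[, 2] == 4, 1])
  expect_setequal(partners, c(0, 7))
})

test_that("strand-exchange templates build correct global pair maps", {
  # plain duplex: two 10-nt chains, one full-length antiparallel block
  sx <- strand_exchange_template(
    c(10, 10),
    list(list(chain_a = 0, interval_a = c(0, 10),
              chain_b = 1, interval_b = c(0, 10))))
  expect_true(pairs_equal(sx$ss$pairs, cbind(0:9, 19:10)))
  expect_equal(sx$ss$chain_breaks, 10L)

  # crossed exchange: every base paired exactly once
  sx <- strand_exchange_template(
    c(10, 10),
    list(list(chain_a = 0, interval_a = c(0, 5),
              chain_b = 1, interval_b = c(5, 10)),
         list(chain_a = 0, interval_a = c(5, 10),
              chain_b = 1, interval_b = c(0, 5))))
  expect_equal(nrow(sx$ss$pairs), 10L)
  expect_equal(sort(c(sx$ss$pairs)), 0:19)
  expect_false(sx$ss$multi_partner_allowed)
  expect_true(pairs_equal(
    sx$ss$pairs,
    rbind(cbind(0:4, 19:15), cbind(5:9, 14:10))))

  # cyclic heterotrimer of half-length blocks: each chain has two partners
  sx <- strand_exchange_template(
    c(8, 8, 8),
    list(list(chain_a = 0, interval_a = c(4, 8), chain_b = 1, interval_b = c(0, 4)),
         list(chain_a = 1, interval_a = c(4, 8), chain_b = 2, interval_b = c(0, 4)),
         list(chain_a = 2, interval_a = c(4, 8), chain_b = 0, interval_b = c(0, 4))))
  expect_equal(nrow(sx$ss$pairs), 12L)
  chain_of <- function(i) findInterval(i, c(0, 8, 16))
  partner_census <- sapply(0:2, function(ch) {
    rows <- chain_of(sx$ss$pairs[, 1]) == ch + 1 | chain_of(sx$ss$pairs[, 2]) == ch + 1
    length(unique(setdiff(chain_of(c(sx$ss$pairs[rows, ])), ch + 1)))
  })
  expect_equal(partner_census, c(2L, 2L, 2L))

  expect_error(
    strand_exchange_template(c(10, 10),
                             list(list(chain_a = 0, interval_a = c(5, 12),
                                       chain_b = 1, interval_b = c(0, 7)))),
    class = "natk_bounds")
})

test_that("tensor files round-trip in dense and sparse form", {
  ss <- parse_dotbracket("((..[[..))..]]")
  tn <- from_secondary_structure(ss, TRUE)
  tn$chain_breaks <- 7L

  dense <- tempfile(fileext = ".tensor")
  write_tensor(tn, dense)
  back <- read_tensor(dense)
  expect_equal(back$A, tn$A)
  expect_equal(back$chain_breaks, 7L)

  sparse <- tempfile(fileext = ".tsv")
  write_tensor_sparse(tn, sparse)
  back <- read_tensor_sparse(sparse)
  expect_equal(back$A, tn$A)
})

test_that("region-pair config files parse", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("- region_a: [0, 3]",
               "  region_b: [5, 8]",
               "  orientation: parallel",
               "- region_a: [10, 12]",
               "  region_b: [14, 16]"), path)
  rps <- read_region_pairs(path)
  expect_length(rps, 2L)
  expect_equal(rps[[1]]$orientation, "parallel")
  expect_equal(rps[[2]]$orientation, "antiparallel")
})
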