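test_that("binary encoding matches the per-base indicator definition", {
  m <- encode_binary("ACGTN")
  expect_equal(dim(m), c(5L, 5L))
  expect_equal(m[1, ], c(A = 1, C = 0, G = 0, T = 0, N = 0))
  expect_equal(m[5, ], c(A = 0, C = 0, G = 0, T = 0, N = 0))
  expect_equal(unname(m[1:4, 1:4]), diag(4))

  set.seed(21)
  for (i in 1:10) {
    s <- random_window()
    be <- encode_binary(s)
    expect_equal(dim(be), c(41L, 5L))
    chars <- strsplit(s, "")[[1]]
    expect_equal(rowSums(be), as.numeric(chars != "N"))
  }
  expect_error(encode_binary("ACGTZ"), "A,C,G,T,N")
})

test_that("k-mer one-hot has the printed dimensionality and frozen order", {
  set.seed(22)
  s <- random_window()
  expect_equal(dim(encode_kmer_onehot(s, 2)), c(40L, 25L))
  expect_equal(dim(encode_kmer_onehot(s, 3)), c(39L, 125L))
  expect_error(encode_kmer_onehot(s, 4), "2 \\(DNC\\) or 3")

  m <- encode_kmer_onehot("AAA", 2)
  expect_equal(dim(m), c(2L, 25L))
  expect_equal(m[, "AA"], c(1, 1))
  expect_equal(rowSums(m), c(1, 1))

  # channel order: lexicographic over A < C < G < N < T
  expect_equal(kmer_alphabet(2)[1:6], c("AA", "AC", "AG", "AN", "AT", "CA"))
  expect_equal(length(kmer_alphabet(3)), 125L)

  # every row one-hot for random windows
  for (i in 1:5) {
    mm <- encode_kmer_onehot(random_window(), 3)
    expect_true(all(rowSums(mm) == 1))
  }
})

test_that("NCP reproduces the chemical-property coordinates exactly", {
  m <- encode_ncp("ACGTN")
  expect_equal(unname(m),
               rbind(c(1, 1, 1), c(0, 0, 1), c(1, 0, 0), c(0, 1, 0),
                     c(0, 0, 0)))
  # x-channel is the purine indicator
  s <- random_window()
  chars <- strsplit(s, "")[[1]]
  expect_equal(encode_ncp(s)[, "x"], as.numeric(chars %in% c("A", "G")))

  # alternating composition: "ACGT" x 10 + "A" has 21 of each property class
  alt <- paste0(strrep("ACGT", 10), "A")
  expect_equal(unname(colSums(encode_ncp(alt))), c(21, 21, 21))
})

test_that("NCPNF appends the cumulative prefix density", {
  m <- encode_ncpnf(strrep("A", 41))
  expect_true(all(m == 1))

  m2 <- encode_ncpnf(paste0("AC", strrep("A", 38), "C"))
  expect_equal(unname(m2[1, ]), c(1, 1, 1, 1))
  expect_equal(unname(m2[2, ]), c(0, 0, 1, 0.5))

  set.seed(23)
  for (i in 1:10) {
    d <- encode_ncpnf(random_window())[, "d"]
    expect_true(all(d > 0 & d <= 1))
    expect_equal(d[[1]], 1)
  }

  expect_equal(ncol(encode_ncpnf("ACC", pad5 = TRUE)), 5L)
  expect_true(all(encode_ncpnf("ACC", pad5 = TRUE)[, 5] == 0))
})

test_that("MMI produces 55 features and matches a brute-force oracle", {
  m <- encode_mmi(strrep("A", 41))
  expect_equal(dim(m), c(55L, 1L))
  expect_equal(m["f_A", 1], 1)
  expect_true(all(m[setdiff(rownames(m), "f_A"), 1] == 0))

  set.seed(24)
  for (i in 1:100) {
    s <- random_window(n_rate = if (i %% 3 == 0) 0.2 else 0.02)
    expect_equal(as.numeric(encode_mmi(s)), mmi_brute(s), tolerance = 1e-12)
  }
})

test_that("encoders are pure and produce the documented shapes", {
  set.seed(25)
  s <- random_window()
  for (scheme in c("BE", "DNC", "TNC", "NCP", "NCPNF", "MMI")) {
    a <- encode_window(s, scheme)
    b <- encode_window(s, scheme)
    expect_identical(a, b)
    expect_equal(unname(dim(a)), as.integer(scheme_shape(scheme)))
    expect_true(all(is.finite(a)))
  }
})

test_that("dataset encoding stacks matrices with aligned labels", {
  ds <- make_dataset(10, seed = 31)
  tn <- encode_dataset(ds, "DNC")
  expect_equal(dim(tn$x), c(10L, 40L, 25L))
  expect_equal(tn$y, ds$label)
  expect_equal(tn$x[4, , ], unname(encode_window(ds$seq[4], "DNC")))

  mmi <- encode_dataset(ds, "MMI")
  expect_equal(dim(mmi$x), c(10L, 55L, 1L))

  expect_error(encode_dataset(ds[0, ], "BE"), "empty")
  mixed <- dplyr::bind_rows(ds, tibble::tibble(id = "s", seq = "ACC",
                                               label = 0L))
  expect_error(encode_dataset(mixed, "BE"), "length")
  expect_error(encode_dataset(ds, "EIIP"), "unknown encoding scheme")
})

test_that("tensor CSV export is flat, named and loss-free", {
  ds <- make_dataset(4, seed = 32)
  tn <- encode_dataset(ds, "NCP")
  tf <- withr::local_tempfile(fileext = ".csv")
  write_tensor_csv(tn, tf)
  back <- readr::read_csv(tf, show_col_types = FALSE)
  expect_equal(nrow(back), 4L)
  expect_equal(ncol(back), 2L + 41L * 3L)
  expect_equal(back$NCP_p1_c1, tn$x[, 1, 1])
  expect_equal(back$NCP_p41_c3, tn$x[, 41, 3])
})
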