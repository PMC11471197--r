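test_that("from-call probes cut L/2 bases around the split", {
  # centered 28-nt junction: probe equals the junction sequence
  call <- toy_call(junction_seq = strrep("ACGT", 7), split_index = 14L)
  pr <- build_probes(call, L = 28)
  expect_equal(pr$sequence, strrep("ACGT", 7))
  expect_equal(pr$split_index, 14L)
  expect_equal(nchar(pr$sequence), 28L)
  # longer junction with off-center split still yields L/2 per side
  js <- paste0(strrep("A", 20), strrep("C", 20))
  call2 <- toy_call(junction_seq = js, split_index = 20L)
  pr2 <- build_probes(call2, L = 28)
  expect_equal(pr2$sequence, paste0(strrep("A", 14), strrep("C", 14)))
  expect_error(build_probes(call, L = 27), "even")
})

test_that("probes with N or short flanks are excluded and reported", {
  calls <- rbind(
    toy_call(call_id = "ok"),
    toy_call(call_id = "hasN",
             junction_seq = paste0(strrep("A", 13), "N", strrep("C", 14))),
    toy_call(call_id = "short", junction_seq = strrep("AC", 5),
             split_index = 5L))
  class(calls) <- c("chimera_calls", "data.frame")
  pr <- build_probes(calls, L = 28)
  expect_equal(pr$probe_id, "ok")
  sk <- attr(pr, "skipped")
  expect_setequal(sk$call_id, c("hasN", "short"))
  expect_true(any(grepl("N", sk$reason)))
  expect_true(any(grepl("flank", sk$reason)))
})

test_that("duplicate probe sequences collapse with call ids recorded", {
  calls <- rbind(toy_call(call_id = "a"), toy_call(call_id = "b"),
                 toy_call(call_id = "c",
                          junction_seq = strrep("GGTA", 7)))
  class(calls) <- c("chimera_calls", "data.frame")
  pr <- build_probes(calls)
  expect_equal(nrow(pr), 2L)
  expect_equal(pr$call_ids[pr$probe_id == "a"], "a;b")
})

test_that("from-genome probes equal the generator's junction sequences", {
  ds <- shared_dataset()
  pr <- build_probes(ds$calls, source = "from-genome", genome = ds$genome,
                     models = ds$models)
  expect_equal(nrow(pr), nrow(ds$calls))
  expect_identical(pr$sequence[match(ds$calls$call_id, pr$probe_id)],
                   ds$calls$junction_seq)
})

test_that("bitap counting follows the Hamming definition", {
  p <- random_probe(28)
  expect_equal(bitap_count(p, p, match_params(k = 0)), 1L)
  mutated <- p
  substr(mutated, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                     substr(p, 10, 10))[1]
  expect_equal(bitap_count(p, mutated, match_params(k = 0)), 0L)
  expect_equal(bitap_count(p, mutated, match_params(k = 1)), 1L)
  # reverse-complement orientation found iff the flag is on
  rc_read <- paste0("TTTT", revcomp(p), "GGGG")
  expect_equal(bitap_count(p, rc_read, match_params(k = 0)), 1L)
  expect_equal(bitap_count(
    p, rc_read, match_params(k = 0, search_reverse_complement = FALSE)), 0L)
  # N in the read never matches
  n_read <- p
  substr(n_read, 3, 3) <- "N"
  expect_equal(bitap_count(p, n_read, match_params(k = 0)), 0L)
  expect_equal(bitap_count(p, n_read, match_params(k = 1)), 1L)
  expect_error(bitap_count("ACGT", "ACGT", match_params(k = 3,
                                                        probe_length = 4)),
               NA)
  expect_error(cpp_k <- bitap_count("ACGT", "ACGT",
                                    structure(list(k = 4L,
                                                   distance_model = "hamming",
                                                   search_reverse_complement
                                                   = FALSE,
                                                   min_flank = 0L),
                                              class = "match_params")),
               "k must")
})

test_that("bitap equals the exhaustive oracle on a small alphabet", {
  # every {A,C}^4 probe against every {A,C}^6 read, both models, k in 0:1
  probes <- apply(expand.grid(rep(list(c("A", "C")), 4)), 1, paste,
                  collapse = "")
  reads <- apply(expand.grid(rep(list(c("A", "C")), 6)), 1, paste,
                 collapse = "")
  for (k in 0:1) for (model in c("hamming", "edit")) {
    prm <- match_params(k = k, distance_model = model, probe_length = 4)
    b <- outer(probes, reads, Vectorize(function(p, r) bitap_count(p, r, prm,
                                                                   2L)))
    n <- outer(probes, reads, Vectorize(function(p, r) naive_count(p, r, prm,
                                                                   2L)))
    expect_identical(b, n)
  }
})

test_that("bitap equals the randomized oracle with embedded mutations", {
  set.seed(19)
  bases <- c("A", "C", "G", "T")
  for (i in 1:300) {
    L <- sample(c(8, 16, 28), 1)
    k <- sample(0:2, 1)
    read <- paste(sample(c(bases, "N"), 100, replace = TRUE,
                         prob = c(rep(0.24, 4), 0.04)), collapse = "")
    probe <- random_probe(L)
    if (runif(1) < 0.6) {  # embed a mutated copy so hits actually occur
      pos <- sample(100 - L, 1)
      pv <- strsplit(probe, "")[[1]]
      nm <- sample(0:3, 1)
      if (nm > 0) for (j in sample(L, nm)) pv[j] <- sample(bases, 1)
      substr(read, pos, pos + L - 1) <- paste(pv, collapse = "")
    }
    for (model in c("hamming", "edit")) {
      prm <- match_params(k = k, distance_model = model, probe_length = L)
      expect_identical(bitap_count(probe, read, prm),
                       naive_count(probe, read, prm))
    }
  }
})

test_that("counts are non-decreasing in k", {
  set.seed(23)
  for (i in 1:50) {
    probe <- random_probe(16)
    read <- paste0(random_probe(40), probe, random_probe(40))
    for (model in c("hamming", "edit")) {
      prev <- -1L
      for (k in 0:3) {
        cur <- bitap_count(probe, read,
                           match_params(k = k, distance_model = model,
                                        probe_length = 16))
        expect_gte(cur, prev)
        prev <- cur
      }
    }
  }
})

test_that("read-level counting: a read contributes at most 1 per probe", {
  probe <- random_probe(28)
  f <- withr::local_tempfile(fileext = ".fastq")
  double_read <- paste0(probe, "ACGTACGTAC", probe)
  write_tmp_fastq(c("r1", "r2"), c(double_read, random_probe(60)), f)
  pr <- data.frame(probe_id = "p1", sequence = probe, split_index = 14L,
                   source = "from-call", call_ids = "p1",
                   stringsAsFactors = FALSE)
  class(pr) <- c("junction_probes", "data.frame")
  counts <- count_sample(pr, f)
  expect_equal(unname(counts), 1L)
  expect_equal(bitap_count(probe, double_read, match_params()), 2L)
})

test_that("count_sample is invariant to read order and file splits", {
  ds <- shared_dataset()
  probes <- build_probes(ds$calls)
  fq <- ds$sheet$fastq[[1]]
  base <- count_sample(probes, fq)
  reads <- read_fastq(fq)
  set.seed(5)
  perm <- sample(length(reads))
  f_perm <- withr::local_tempfile(fileext = ".fastq")
  write_tmp_fastq(names(reads)[perm], unname(reads)[perm], f_perm)
  expect_identical(count_sample(probes, f_perm), base)
  # split across two files
  half <- seq_len(length(reads) %/% 2)
  fa <- withr::local_tempfile(fileext = ".fastq")
  fb <- withr::local_tempfile(fileext = ".fastq")
  write_tmp_fastq(names(reads)[half], unname(reads)[half], fa)
  write_tmp_fastq(names(reads)[-half], unname(reads)[-half], fb)
  expect_identical(count_sample(probes, c(fa, fb)), base)
  # tiny chunks traverse the chunking path
  expect_identical(count_sample(probes, fq, chunk_size = 97L), base)
})

test_that("empty samples give all-zero rows and cohorts keep sample order", {
  ds <- shared_dataset()
  probes <- build_probes(ds$calls)
  f0 <- withr::local_tempfile(fileext = ".fastq")
  file.create(f0)
  expect_true(all(count_sample(probes, f0) == 0L))
  sheet1 <- sample_sheet(data.frame(
    sample_id = "s1", group = "case",
    fastq = I(list(ds$sheet$fastq[[1]])), stringsAsFactors = FALSE))
  mt1 <- count_cohort(probes, sheet1)
  expect_equal(unname(mt1$counts[1, ]),
               unname(count_sample(probes, ds$sheet$fastq[[1]])))
  # permuting sample-sheet rows permutes rows only
  perm <- rev(seq_len(nrow(ds$sheet)))
  mt_f <- count_cohort(probes, ds$sheet)
  mt_r <- count_cohort(probes, ds$sheet[perm, ])
  expect_identical(mt_r$counts[rownames(mt_f$counts), ], mt_f$counts)
  dup <- ds$sheet[c(1, 1), ]
  expect_error(count_cohort(probes, dup), "duplicate")
})

test_that("match table is invariant under global reverse complement", {
  ds <- shared_dataset()
  probes <- build_probes(ds$calls)
  fq <- ds$sheet$fastq[[2]]
  base <- count_sample(probes, fq)
  reads <- read_fastq(fq)
  f_rc <- withr::local_tempfile(fileext = ".fastq")
  write_tmp_fastq(names(reads), revcomp(unname(reads)), f_rc)
  expect_identical(count_sample(probes, f_rc), base)
})
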