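toy_attrs <- function(tids, gids = tids, biotype = "lincRNA") {
  data.frame(transcript_id = tids, gene_id = gids,
             gene_symbol = paste0("SYM_", gids), biotype = biotype,
             stringsAsFactors = FALSE)
}

test_that("window lookup enumerates exact occurrences on both strands", {
  # "ACGTACGT" occurs at offsets 0, 4, 8 of a 16-nt repeat; it is its own
  # reverse complement, so each occurrence is also reported on "-"
  idx <- index_transcripts(c(T1 = "ACGTACGTACGTACGT"), toy_attrs("T1"),
                           probe_length = 8)
  hits <- lookup_window(idx, "ACGTACGT")
  expect_equal(sort(hits$offset[hits$strand == "+"]), c(0, 4, 8))
  expect_equal(sort(hits$offset[hits$strand == "-"]), c(0, 4, 8))

  # non-palindromic probe equal to the reverse complement of a window
  idx2 <- index_transcripts(c(T1 = "AAAACCCCGGGGTTTT"), toy_attrs("T1"),
                            probe_length = 8)
  hits2 <- lookup_window(idx2, "GGGGTTTT")   # revcomp = AAAACCCC at offset 0
  expect_true(any(hits2$strand == "-" & hits2$offset == 0))
  expect_true(any(hits2$strand == "+" & hits2$offset == 8))
  expect_error(lookup_window(idx2, "ACGT"), "length")
})

test_that("index rejects invalid sequences and short probe lengths", {
  expect_error(index_transcripts(c(T1 = "ACGTXCGTAA"), toy_attrs("T1"), 8),
               "outside A/C/G/T/N")
  expect_error(index_transcripts(c(T1 = "ACGTACGTAA"), toy_attrs("T1"), 4),
               ">= 8")
  expect_error(index_transcripts(c(T1 = "ACGTACGTAA"), toy_attrs("T2"), 8),
               "misses transcript")
})

test_that("probe mapping agrees with a naive string scan", {
  set.seed(401)
  n_tx <- 50
  tx <- vapply(seq_len(n_tx), function(i)
    paste(sample(c("A", "C", "G", "T"), sample(100:300, 1), replace = TRUE),
          collapse = ""), character(1))
  names(tx) <- sprintf("T%02d", seq_len(n_tx))
  attrs <- toy_attrs(names(tx))
  idx <- index_transcripts(tx, attrs, probe_length = 25)
  # probes: substrings, reverse complements of substrings, and random decoys
  mk_sub <- function() {
    t <- sample(n_tx, 1); o <- sample(nchar(tx[t]) - 24, 1)
    substring(tx[t], o, o + 24)
  }
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  seqs <- c(replicate(80, mk_sub()),
            vapply(replicate(60, mk_sub()), rc, character(1)),
            replicate(60, paste(sample(c("A", "C", "G", "T"), 25,
                                       replace = TRUE), collapse = "")))
  probes <- data.frame(probe_id = sprintf("p%03d", seq_along(seqs)),
                       probeset_id = "ps1", sequence = unname(seqs),
                       stringsAsFactors = FALSE)
  maps <- map_probes(probes, idx)

  naive_hits <- function(p) {
    sum(vapply(tx, function(s) {
      f <- gregexpr(p, s, fixed = TRUE)[[1]]
      r <- gregexpr(rc(p), s, fixed = TRUE)[[1]]
      sum(f > 0) + sum(r > 0)
    }, numeric(1)))
  }
  expected <- vapply(probes$sequence, naive_hits, numeric(1))
  expect_equal(maps$summary$n_hits, unname(expected))
  expect_equal(maps$summary$is_perfect, unname(expected) > 0)
})

test_that("specificity and perfection flags follow their definitions", {
  tx <- c(T1 = paste0("AAAA", "ACGTACGTACGTACGTACGTACGTA", "GGGG"),
          T2 = paste0("TTTT", "ACGTACGTACGTACGTACGTACGTA", "CCCC"),
          T3 = paste0(strrep("GATC", 10)))
  attrs <- toy_attrs(names(tx), gids = c("gA", "gB", "gC"))
  idx <- index_transcripts(tx, attrs, probe_length = 25)
  shared <- "ACGTACGTACGTACGTACGTACGTA"          # in genes gA and gB
  only_t3 <- substr(strrep("GATC", 10), 2, 26)   # unique to gC
  mism <- paste0("ACGTACGTACGTCCGTACGTACGTA")    # 1 mismatch to shared
  probes <- data.frame(probe_id = c("p1", "p2", "p3"),
                       probeset_id = "ps1",
                       sequence = c(only_t3, shared, mism),
                       stringsAsFactors = FALSE)
  maps <- map_probes(probes, idx)
  s <- maps$summary
  expect_true(s$is_perfect[1] && s$is_specific[1])
  expect_true(s$is_perfect[2])
  expect_false(s$is_specific[2])
  expect_equal(s$n_hits[3], 0L)
  expect_false(s$is_perfect[3])
  expect_error(map_probes(data.frame(probe_id = "bad", probeset_id = "ps",
                                     sequence = "ACGT",
                                     stringsAsFactors = FALSE), idx),
               "bad")
})

test_that("gene retention applies the >=4-probe, perfect, specific, biotype rules", {
  set.seed(77)
  mk_tx <- function() paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                            collapse = "")
  tx <- c(T1 = mk_tx(), T2 = mk_tx(), T3 = mk_tx())
  attrs <- data.frame(transcript_id = c("T1", "T2", "T3"),
                      gene_id = c("g4", "g3", "gPC"),
                      gene_symbol = c("S4", "S3", "SPC"),
                      biotype = c("antisense", "lincRNA", "protein_coding"),
                      stringsAsFactors = FALSE)
  idx <- index_transcripts(tx, attrs, probe_length = 25)
  sub <- function(t, o) substring(tx[t], o, o + 24)
  probes <- data.frame(
    probe_id = sprintf("p%02d", 1:12),
    probeset_id = "ps",
    sequence = c(sub("T1", 1), sub("T1", 40), sub("T1", 80), sub("T1", 120),
                 sub("T2", 1), sub("T2", 40), sub("T2", 80),
                 sub("T3", 1), sub("T3", 40), sub("T3", 80), sub("T3", 120),
                 sub("T3", 160)),
    stringsAsFactors = FALSE)
  maps <- map_probes(probes, idx)
  tab <- filter_mappings(maps, attrs)
  # g4 retained (4 qualifying probes, whitelisted biotype)
  expect_equal(tab$gene_id, "g4")
  expect_equal(tab$n_probes, 4L)
  # g3 excluded (3 probes), gPC excluded (5 probes, protein_coding)
  expect_false("g3" %in% tab$gene_id)
  expect_false("gPC" %in% tab$gene_id)
  # empty mapping list gives an empty table, not an error
  empty <- map_probes(probes[0, ], idx)
  expect_equal(nrow(filter_mappings(empty, attrs)), 0L)
  # mapping is order-independent over probes
  maps_perm <- map_probes(probes[sample(nrow(probes)), ], idx)
  tab_perm <- filter_mappings(maps_perm, attrs)
  expect_equal(tab_perm, tab)
})

test_that("probe aggregation takes per-sample arithmetic means", {
  annot <- structure(
    data.frame(gene_id = c("gA", "gB"), gene_symbol = c("A", "B"),
               biotype = "lincRNA",
               probe_ids = c("p1,p2", "p3"), n_probes = c(2L, 1L),
               stringsAsFactors = FALSE),
    class = c("lncrna_annotation", "data.frame"))
  pm <- matrix(c(2, 4, 7, 4, 8, 1), nrow = 3,
               dimnames = list(c("p1", "p2", "p3"), c("s1", "s2")))
  agg <- aggregate_to_lncrna(pm, annot)
  expect_equal(agg["gA", ], c(s1 = 3, s2 = 6))     # mean of (2,4) and (4,8)
  expect_equal(agg["gB", ], pm["p3", ])            # single-probe gene copies
  expect_error(aggregate_to_lncrna(pm[1:2, ], annot), "p3")

  # random 10-probe gene equals independently computed column means,
  # and aggregation commutes with sample subsetting
  set.seed(5)
  pm10 <- matrix(rnorm(60), nrow = 10,
                 dimnames = list(sprintf("q%02d", 1:10), sprintf("s%d", 1:6)))
  a10 <- structure(
    data.frame(gene_id = "gX", gene_symbol = "X", biotype = "TEC",
               probe_ids = paste(rownames(pm10), collapse = ","),
               n_probes = 10L, stringsAsFactors = FALSE),
    class = c("lncrna_annotation", "data.frame"))
  expect_equal(aggregate_to_lncrna(pm10, a10)["gX", ], colMeans(pm10))
  expect_equal(aggregate_to_lncrna(pm10[, 2:4], a10),
               aggregate_to_lncrna(pm10, a10)[, 2:4, drop = FALSE])
})

test_that("synthetic universe is reannotated with perfect precision and recall", {
  u <- simulate_probe_universe(probe_universe_config(n_clean_lncrna = 25,
                                                     seed = 19))
  idx <- index_transcripts(u$transcripts, u$attrs, probe_length = 25)
  maps <- map_probes(u$probes, idx)
  tab <- filter_mappings(maps, u$attrs)
  expect_setequal(tab$gene_id, u$truth$clean_genes)
  expect_equal(mean(tab$gene_id %in% u$truth$clean_genes), 1)   # precision
  expect_equal(mean(u$truth$clean_genes %in% tab$gene_id), 1)   # recall
})
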