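test_that("exact substrings align to their origin on either strand", {
  ref <- toy_ref()
  g <- ref$genome
  s <- substr(g$sequence, 100L, 130L)
  al <- align_sequence(s, g)
  expect_true(al$mapped)
  expect_equal(al$genome_start, 100L)
  expect_equal(al$strand, "H")
  expect_equal(al$n_mismatch, 0L)

  s2 <- reverse_complement(substr(g$sequence, 200L, 230L))
  al2 <- align_sequence(s2, g)
  expect_equal(al2$genome_start, 200L)
  expect_equal(al2$strand, "L")
})

test_that("strand involution: the reverse complement maps to the same interval", {
  ref <- toy_ref()
  g <- ref$genome
  with_seed_helper(21L, {
    for (i in 1:10) {
      st <- sample(1:(g$length - 30L), 1L)
      s <- substr(g$sequence, st, st + 29L)
      a <- align_sequence(s, g)
      b <- align_sequence(reverse_complement(s), g)
      expect_equal(a$genome_start, b$genome_start)
      expect_equal(a$length, b$length)
      expect_setequal(c(a$strand, b$strand), c("H", "L"))
    }
  })
})

test_that("single mismatches are located and encoded in read coordinates", {
  ref <- toy_ref()
  g <- ref$genome
  s <- substr(g$sequence, 500L, 529L)
  sv <- strsplit(s, "")[[1L]]
  sv[24L] <- setdiff(c("A", "C", "G", "T"), sv[24L])[1L]
  mut <- paste(sv, collapse = "")
  al <- align_sequence(mut, g)
  expect_equal(al$n_mismatch, 1L)
  expect_equal(al$mm_pos, 24L)
  expect_equal(al$mm_base, sv[24L])
  # on the light strand the mismatch position counts from the read's 5' end
  mut_l <- reverse_complement(mut)
  al_l <- align_sequence(mut_l, g)
  expect_equal(al_l$strand, "L")
  expect_equal(al_l$mm_pos, 30L - 24L + 1L)
  expect_equal(al_l$mm_base, chartr("ACGT", "TGCA", sv[24L]))
})

test_that("reads containing N never map", {
  ref <- toy_ref()
  s <- substr(ref$genome$sequence, 300L, 329L)
  substr(s, 5L, 5L) <- "N"
  expect_false(align_sequence(s, ref$genome)$mapped)
})

test_that("equally good placements break ties deterministically and set multimap", {
  # genome with an exact repeat: unit of 30 nt placed twice
  unit <- with_seed_helper(33L, paste(sample(c("A", "C", "G", "T"), 30L,
                                             replace = TRUE), collapse = ""))
  filler <- with_seed_helper(34L, paste(sample(c("A", "C", "G", "T"), 100L,
                                               replace = TRUE), collapse = ""))
  gseq <- paste0(filler, unit, filler, unit, filler)
  genome <- structure(list(name = "rep", sequence = gseq,
                           length = nchar(gseq)), class = "mito_genome")
  al <- align_sequence(unit, genome)
  expect_true(al$multimap)
  expect_equal(al$genome_start, 101L)  # smallest start wins
  expect_equal(al$strand, "H")         # H before L
})

test_that("the aligner agrees with an exhaustive scan on planted queries", {
  ref <- toy_ref()
  g <- ref$genome
  with_seed_helper(55L, {
    for (i in 1:150) {
      k <- sample(0:2, 1L)
      q <- plant_query(g$sequence, k)
      got <- align_sequence(q, g)
      want <- oracle_scan(q, g$sequence)
      expect_equal(got$mapped, want$mapped, info = q)
      if (want$mapped) {
        expect_equal(got$genome_start, want$genome_start, info = q)
        expect_equal(got$strand, want$strand, info = q)
        expect_equal(got$n_mismatch, want$n_mismatch, info = q)
        expect_equal(got$multimap, want$multimap, info = q)
      }
    }
  })
})

test_that("CCA rescue trims the motif and requires a tRNA end", {
  gs <- cca_fixture(trna_strand = "H")
  g <- gs$genome
  # sense fragment of the tRNA 3' end plus non-templated CCA
  read <- paste0(substr(g$sequence, 80L, 110L), "CCA")
  expect_false(align_sequence(read, g)$mapped)  # downstream flank is TTT
  al <- cca_rescue(read, g, gs)
  expect_true(al$mapped)
  expect_true(al$cca_added)
  expect_equal(al$genome_start, 80L)
  expect_equal(al$strand, "H")
  expect_equal(al$length, 31L)           # shortened by exactly 3 nt
  expect_equal(al$n_mismatch, 0L)        # rescue never carries mismatches
  expect_equal(al$sequence, read)

  # trimmed form mapping inside a protein-coding gene: rejected
  read_pc <- paste0(substr(g$sequence, 140L, 170L), "CCA")
  if (!align_sequence(read_pc, g)$mapped) {
    expect_false(cca_rescue(read_pc, g, gs)$mapped)
  }
  expect_error(cca_rescue(substr(g$sequence, 80L, 110L), g, gs),
               "not ending in CCA")
})

test_that("antisense CCA rescue anchors at the tRNA gene's 5' end", {
  gs <- cca_fixture(trna_strand = "L")
  g <- gs$genome
  # an H-strand read antisense to the L tRNA, 3' end at the gene's 5' end
  read <- paste0(substr(g$sequence, 80L, 110L), "CCA")
  expect_false(align_sequence(read, g)$mapped)
  al <- cca_rescue(read, g, gs)
  expect_true(al$mapped)
  expect_true(al$cca_added)
  expect_equal(al$strand, "H")  # antisense to the L-strand gene
})

test_that("align_matrix reports rescue, drops short reads, and closes the strand split", {
  gs <- cca_fixture("H")
  g <- gs$genome
  d <- tempfile(); dir.create(d)
  reads <- c(substr(g$sequence, 45L, 80L),                 # direct, H
             reverse_complement(substr(g$sequence, 140L, 170L)),  # direct, L
             paste0(substr(g$sequence, 80L, 110L), "CCA"), # rescue
             strrep("A", 10L),                             # too short
             strrep("ACGT", 10L))                          # foreign
  f <- write_plain_fastq(reads, rep(5L, 5L), file.path(d, "mix.fastq"))
  m <- build_count_matrix(f, mode = "sRNA", cutoff = 1L)
  res <- align_matrix(m, g, gs)
  aln <- res$alignments
  expect_equal(sum(aln$mapped), 3L)
  expect_equal(sum(aln$cca_added), 1L)
  expect_false(aln$mapped[aln$sequence == strrep("A", 10L)])
  st <- res$stats
  expect_equal(st$pct_heavy_sequences + st$pct_light_sequences, 100)
  expect_equal(st$pct_heavy_reads + st$pct_light_reads, 100)
  expect_equal(st$n_sequences, 5L)
})
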