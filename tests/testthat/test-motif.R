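# ChoRE consensus-PWM construction and upstream scanning

test_that("consensus-to-PWM construction puts unit weight on informative bases", {
  pwm <- pwmFromConsensus("CA")
  expect_equal(dim(pwm), c(4L, 2L))
  expect_equal(unname(pwm["C", 1]), 1)
  expect_equal(unname(pwm["A", 2]), 1)
  expect_equal(sum(pwm), 2)

  pwmN <- pwmFromConsensus("N")
  expect_equal(sum(pwmN), 0)
  expect_equal(attr(pwmN, "n_informative"), 0)

  pwmB <- pwmFromConsensus(choreMotifs()$chore_b)
  expect_equal(ncol(pwmB), 17)
  expect_equal(attr(pwmB, "n_informative"), 12)
  expect_equal(sum(pwmB), 12)   # max achievable score

  expect_error(pwmFromConsensus("CAX"), "position 3")
})

test_that("match-fraction scoring admits one informative mismatch at 0.90", {
  pwmB <- pwmFromConsensus(choreMotifs()$chore_b, "chore_b")
  exact <- paste0("CACACC", "AAAAA", "CACGCG")
  h <- scanSequence(exact, pwmB, both_strands = FALSE)
  expect_equal(h$score, 1.0)
  expect_equal(h$start, 1L)

  # the published Sun2-type site: one informative mismatch, 11/12
  one_mm <- paste0("CACACT", "CGGCC", "CACGCG")
  h1 <- scanSequence(one_mm, pwmB, both_strands = FALSE)
  expect_equal(h1$score, 11 / 12)
  expect_gte(h1$score, 0.90)

  two_mm <- paste0("CACATT", "CGGCC", "CACGCG")
  expect_equal(nrow(scanSequence(two_mm, pwmB, both_strands = FALSE)), 0)
  # letters at N positions never change the score
  set.seed(31)
  for (i in 1:5) {
    var_n <- paste0("CACACC", randomDna(5), "CACGCG")
    expect_equal(scanSequence(var_n, pwmB, both_strands = FALSE)$score, 1.0)
  }

  # too-short sequence: empty result
  expect_equal(nrow(scanSequence("CACACC", pwmB)), 0)
})

test_that("reverse-strand hits appear at mirrored coordinates with forward letters", {
  pwmB <- pwmFromConsensus(choreMotifs()$chore_b, "chore_b")
  site <- paste0("CACACC", "GGGGG", "CACGCG")
  seq <- paste0("TTTT", revcompStr(site), "AA")
  h <- scanSequence(seq, pwmB)
  expect_equal(nrow(h), 1)
  expect_equal(h$strand, "-")
  expect_equal(c(h$start, h$end), c(5L, 21L))
  expect_equal(h$match, revcompStr(site))   # forward-strand letters

  # strand symmetry: a + hit on seq is a - hit on its reverse complement
  set.seed(32)
  for (i in 1:10) {
    s <- paste0(randomDna(20), site, randomDna(20))
    fwd <- scanSequence(s, pwmB)
    rev <- scanSequence(revcompStr(s), pwmB)
    expect_equal(nrow(fwd), nrow(rev))
    n <- nchar(s)
    expect_setequal(paste(n - rev$end + 1, n - rev$start + 1,
                          chartr("+-", "-+", rev$strand)),
                    paste(fwd$start, fwd$end, fwd$strand))
  }
})

test_that("our scanner agrees with Biostrings::matchPWM at min.score 90%", {
  library(Biostrings)
  pwmB <- pwmFromConsensus(choreMotifs()$chore_b, "chore_b")
  set.seed(33)
  seq <- paste0(randomDna(300), "CACACT", "CGGCC", "CACGCG", randomDna(300))
  ours <- scanSequence(seq, pwmB, both_strands = FALSE)
  ref <- matchPWM(unitScale(pwmB + 1e-9), DNAString(seq), min.score = "90%")
  expect_equal(ours$start, start(ref))
})

test_that("upstream extraction honours strand, coordinates, and truncation", {
  chr <- paste(rep("ACGT", 2500), collapse = "")   # 10 kb
  genome <- Biostrings::DNAStringSet(c(chrA = chr))
  plus <- list(chromosome = "chrA", tss_bp = 3000, strand = "+",
               gene_id = "gp")
  up <- extractUpstream(plus, genome)
  expect_equal(c(up$start_bp, up$end_bp), c(1000, 2999))
  expect_equal(up$seq, toupper(substring(chr, 1000, 2999)))

  minus <- list(chromosome = "chrA", tss_bp = 3000, strand = "-",
                gene_id = "gm")
  upm <- extractUpstream(minus, genome)
  expect_equal(c(upm$start_bp, upm$end_bp), c(3001, 5000))
  expect_equal(upm$seq, revcompStr(toupper(substring(chr, 3001, 5000))))

  short <- list(chromosome = "chrA", tss_bp = 100, strand = "+")
  expect_warning(ups <- extractUpstream(short, genome), "truncated")
  expect_equal(c(ups$start_bp, ups$end_bp), c(1, 99))

  expect_error(extractUpstream(list(chromosome = "chrB", tss_bp = 5,
                                    strand = "+"), genome),
               "chrB")
})

test_that("planted motifs are recovered with genomic coordinates, both strands", {
  set.seed(34)
  site <- paste0("CACACC", "TTTTT", "CACGCG")
  # chromosome: random 9 kb with the site planted at 2500-2516 (forward)
  chr <- randomDna(9000)
  substr(chr, 2500, 2516) <- site
  genome <- Biostrings::DNAStringSet(c(c1 = chr))
  genes <- GenomicRanges::GRanges("c1",
                                  IRanges::IRanges(c(4000, 4000), c(6000, 6000)),
                                  strand = c("+", "-"))
  genes$gene_id <- c("gplus", "gminus")
  genes$tss_bp <- c(4000, 4000)   # + gene upstream 2000-3999 holds the site
  names(genes) <- genes$gene_id
  hits <- scanGeneSet(genes, genome, motifs = list(chore_b = choreMotifs()$chore_b))
  gp <- hits[hits$gene_id == "gplus" & hits$score == 1, ]
  expect_equal(nrow(gp), 1)
  expect_equal(c(gp$start_bp, gp$end_bp), c(2500, 2516))
  expect_equal(gp$strand, "+")
  expect_equal(gp$match, site)
  # the minus gene's upstream window (4001-6000) does not contain the site
  expect_false(any(hits$gene_id == "gminus" & hits$score == 1))

  # plant on the reverse strand inside the minus gene's window
  chr2 <- randomDna(9000)
  substr(chr2, 5000, 5016) <- revcompStr(site)
  hits2 <- scanGeneSet(genes, Biostrings::DNAStringSet(c(c1 = chr2)),
                       motifs = list(chore_b = choreMotifs()$chore_b))
  gm <- hits2[hits2$gene_id == "gminus" & hits2$score == 1, ]
  expect_equal(nrow(gm), 1)
  expect_equal(c(gm$start_bp, gm$end_bp), c(5000, 5016))
  expect_equal(gm$strand, "-")

  # empty gene list -> empty table
  expect_equal(nrow(scanGeneSet(genes[0], genome)), 0)
})

test_that("random-sequence hit counts match the closed-form probability", {
  # P(>= 11 of 12 informative positions match) for a uniform random window
  p_hit <- stats::dbinom(12, 12, 0.25) + stats::dbinom(11, 12, 0.25)
  pwmB <- pwmFromConsensus(choreMotifs()$chore_b, "chore_b")
  set.seed(35)
  n_genes <- 50; len <- 2000; L <- 17
  windows_per_seq <- 2 * (len - L + 1)
  hits <- sum(vapply(seq_len(n_genes), function(i)
    nrow(scanSequence(randomDna(len), pwmB)), numeric(1)))
  expected <- n_genes * windows_per_seq * p_hit
  tol <- 3 * sqrt(n_genes * windows_per_seq * p_hit * (1 - p_hit))
  expect_lt(abs(hits - expected), tol + 1)
})
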