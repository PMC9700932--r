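# helpers to write a small VCF and to build call sets in code ------------

writeMiniVcf <- function(records, samples = c("s1", "s2"), path = NULL) {
  if (is.null(path)) path <- tempfile(fileext = ".vcf")
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1,length=100000>",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"q\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"f\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"m\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, records), path)
  path
}

rec <- function(pos, ref, alt, qual = 100, dp = 20, qd = 10, fs = 5,
                mq = 50, gts = c("0/1", "1/1")) {
  paste(c("1", pos, ".", ref, alt, qual, ".",
          sprintf("DP=%d;QD=%s;FS=%s;MQ=%s", dp, qd, fs, mq), "GT", gts),
        collapse = "\t")
}

makeCallset <- function(tissue, chrom, pos, ref, alt, geno) {
  list(tissue = tissue,
       variants = data.frame(chrom = chrom, pos = pos, ref = ref,
                             alt = alt,
                             class = ifelse(nchar(ref) == 1 &
                                            nchar(alt) == 1,
                                            "SNP", "INDEL"),
                             stringsAsFactors = FALSE),
       geno = geno, nRemoved = 0L,
       removedBy = c(QUAL = 0L, DP = 0L, QD = 0L, FS = 0L, MQ = 0L))
}

test_that("record QC applies strict thresholds in both direction modes", {
  path <- writeMiniVcf(c(
    rec(100, "A", "T", qual = 10),              # fails QUAL
    rec(200, "A", "T", qual = 30),              # boundary: removed
    rec(300, "A", "T", qual = 30.5),            # passes
    rec(400, "A", "T", dp = 4),                 # boundary DP: removed
    rec(500, "A", "T", qd = 2),                 # fails QD
    rec(600, "A", "T", fs = 60),                # fails FS (standard mode)
    rec(700, "A", "T", mq = 20),                # fails MQ (standard mode)
    rec(800, "A", "AT"),                        # insertion, passes
    rec(900, "ATT", "A"),                       # deletion, passes
    rec(1000, "A", "T", fs = 60, mq = 20)       # passes only literal mode
  ))
  cs <- readTissueVcf(path)
  expect_equal(cs$variants$pos, c(300, 800, 900))
  expect_equal(cs$variants$class, c("SNP", "INDEL", "INDEL"))
  expect_equal(cs$nRemoved, 7)
  expect_equal(unname(cs$removedBy[c("QUAL", "DP", "QD", "FS", "MQ")]),
               c(2L, 1L, 1L, 2L, 2L))

  # literal mode flips FS/MQ retention (FS > 30 and MQ < 35 kept)
  csL <- readTissueVcf(path, qcThresholds(literal = TRUE))
  expect_equal(csL$variants$pos, 1000)
  expect_error(readTissueVcf(tempfile()), "no such VCF")
  expect_error(qcThresholds(qual = -1), "non-negative")
})

test_that("genotype dosages survive parsing including missing calls", {
  path <- writeMiniVcf(c(
    rec(100, "A", "T", gts = c("0/0", "./.")),
    rec(200, "G", "C", gts = c("0|1", "1/1"))
  ))
  cs <- readTissueVcf(path, thresholds = NULL)
  expect_equal(unname(cs$geno[1, ]), c(0L, NA))
  expect_equal(unname(cs$geno[2, ]), c(1L, 2L))
})

test_that("merge takes the unique union with per-tissue presence", {
  g <- function(...) matrix(c(...), ncol = 2, byrow = TRUE,
                            dimnames = list(NULL, c("s1", "s2")))
  csA <- makeCallset("liver", "1", c(100, 200), c("A", "G"),
                     c("T", "C"), g(0, 1, 2, 2))
  csB <- makeCallset("muscle", "1", c(100, 300), c("A", "T"),
                     c("T", "G"), g(0, 1, 1, 0))
  uvt <- mergeUnique(list(csA, csB))
  expect_equal(nrow(variants(uvt)), 3)
  expect_equal(unname(rowSums(tissuePresence(uvt))), c(2, 1, 1))

  # identical variant present in both tissues collapses to one row
  copies <- lapply(1:5, function(i) { x <- csA; x$tissue <- paste0("t", i); x })
  uvt5 <- mergeUnique(copies)
  expect_equal(nrow(variants(uvt5)), 2)
  expect_true(all(rowSums(tissuePresence(uvt5)) == 5))

  # disjoint sets of sizes 10 and 20 give 30 unique rows
  csC <- makeCallset("a", "1", seq(1000, by = 10, length.out = 10),
                     "A", "T", matrix(1, 10, 2,
                                      dimnames = list(NULL, c("s1", "s2"))))
  csD <- makeCallset("b", "1", seq(5000, by = 10, length.out = 20),
                     "A", "T", matrix(1, 20, 2,
                                      dimnames = list(NULL, c("s1", "s2"))))
  expect_equal(nrow(variants(mergeUnique(list(csC, csD)))), 30)

  # conflicting ref at the same position/alt is a data-integrity error
  csE <- makeCallset("x", "1", 100, "AC", "T", g(0, 1))
  expect_error(mergeUnique(list(csA, csE)), "conflicting ref")
})

test_that("merge is idempotent, order-invariant, and matches a set oracle", {
  set.seed(42)
  tissues <- paste0("t", 1:4)
  pool <- data.frame(pos = seq(100, by = 7, length.out = 60),
                     ref = sample(c("A", "C", "G", "T"), 60, TRUE))
  pool$alt <- vapply(pool$ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1))
  sets <- lapply(tissues, function(t) {
    take <- sort(sample(60, sample(20:40, 1)))
    makeCallset(t, "1", pool$pos[take], pool$ref[take], pool$alt[take],
                matrix(sample(0:2, 2 * length(take), TRUE),
                       ncol = 2, dimnames = list(NULL, c("s1", "s2"))))
  })
  uvt <- mergeUnique(sets)
  oracle <- unique(unlist(lapply(sets, function(cs)
    paste(cs$variants$pos, cs$variants$ref, cs$variants$alt))))
  expect_equal(nrow(variants(uvt)), length(oracle))
  uvtRev <- mergeUnique(rev(sets))
  expect_equal(variants(uvt), variants(uvtRev))
  expect_equal(tissuePresence(uvt),
               tissuePresence(uvtRev)[, colnames(tissuePresence(uvt))])
})

test_that("cross-tissue genotype conflicts resolve by majority, ties missing", {
  g1 <- matrix(c(0L, 1L), 1, 2, dimnames = list(NULL, c("s1", "s2")))
  g2 <- matrix(c(2L, 1L), 1, 2, dimnames = list(NULL, c("s1", "s2")))
  g3 <- matrix(c(2L, 1L), 1, 2, dimnames = list(NULL, c("s1", "s2")))
  cs <- lapply(1:3, function(i)
    makeCallset(paste0("t", i), "1", 100, "A", "T",
                list(g1, g2, g3)[[i]]))
  uvt <- mergeUnique(cs)
  expect_equal(unname(genotypes(uvt)[1, "s1"]), 2L)  # 2:1 majority
  expect_equal(unname(genotypes(uvt)[1, "s2"]), 1L)
  tie <- mergeUnique(cs[1:2])
  expect_true(is.na(genotypes(tie)[1, "s1"]))        # 1:1 tie
})

test_that("MAF/call-rate filter honours thresholds and directions", {
  geno <- rbind(
    rep(c(1L, 2L), 5),            # alt freq 0.75 -> maf 0.25
    c(rep(1L, 10)),               # maf 0.5, full call rate
    c(1L, 1L, rep(NA, 8)),        # call rate 0.2
    c(rep(0L, 5), rep(1L, 5)),    # maf 0.25
    c(rep(NA, 5), rep(1L, 5))     # maf 0.5, call rate 0.5 exactly
  )
  colnames(geno) <- paste0("s", 1:10)
  cs <- makeCallset("t1", "1", c(10, 20, 30, 40, 50), "A", "T", geno)
  uvt <- mergeUnique(list(cs))
  expect_equal(variants(uvt)$maf, c(0.25, 0.5, 0.5, 0.25, 0.5))
  filt <- filterMafCallrate(uvt)
  expect_equal(variants(filt)$pos, 20)   # call rate 0.5 is strictly out
  flipped <- filterMafCallrate(uvt, keepAboveMaf = FALSE)
  expect_equal(variants(flipped)$pos, c(10, 40))
  expect_warning(filterMafCallrate(uvt, mafThreshold = 0.9), "no variants")

  # brute-force retention count on a random fixture
  set.seed(7)
  gr <- matrix(sample(c(0:2, NA), 100 * 10, TRUE,
                      prob = c(.3, .3, .3, .1)), 100, 10,
               dimnames = list(NULL, paste0("s", 1:10)))
  csr <- makeCallset("t1", "1", seq_len(100), "A", "T", gr)
  ur <- mergeUnique(list(csr))
  kept <- nrow(variants(filterMafCallrate(ur, 0.3, 0.6)))
  brute <- sum(vapply(seq_len(100), function(i) {
    x <- gr[i, ]; nm <- sum(!is.na(x))
    if (nm == 0) return(FALSE)
    af <- sum(x, na.rm = TRUE) / (2 * nm)
    maf <- min(af, 1 - af)
    maf >= 0.3 && (nm / 10) > 0.6
  }, logical(1)))
  expect_equal(kept, brute)
})

test_that("allelic chi-square matches hand values and the O-E oracle", {
  mkUvt <- function(genoH, genoL) {
    geno <- cbind(genoH, genoL)
    colnames(geno) <- c(paste0("h", seq_len(ncol(genoH))),
                        paste0("l", seq_len(ncol(genoL))))
    mergeUnique(list(makeCallset("t1", "1", seq_len(nrow(geno)), "A",
                                 "T", geno)))
  }
  # complete separation: 9v9 animals, 18 vs 0 alt alleles -> chi2 = 36
  uvt <- mkUvt(matrix(2L, 1, 9), matrix(0L, 1, 9))
  a <- allelicAssociation(uvt, paste0("h", 1:9), paste0("l", 1:9))
  expect_equal(a$chi2, 36)
  expect_true(a$significant)

  # identical allele counts: null
  uvt0 <- mkUvt(matrix(1L, 1, 9), matrix(1L, 1, 9))
  a0 <- allelicAssociation(uvt0, paste0("h", 1:9), paste0("l", 1:9))
  expect_equal(a0$chi2, 0)
  expect_equal(a0$p, 1)

  # monomorphic variant: chi2 0, p 1, no error
  uvtM <- mkUvt(matrix(0L, 1, 9), matrix(0L, 1, 9))
  aM <- allelicAssociation(uvtM, paste0("h", 1:9), paste0("l", 1:9))
  expect_equal(aM$chi2, 0)
  expect_equal(aM$p, 1)

  # randomized suite against the sum (O-E)^2/E oracle
  set.seed(11)
  gH <- matrix(sample(0:2, 50 * 9, TRUE), 50, 9)
  gL <- matrix(sample(0:2, 50 * 9, TRUE, prob = c(.5, .3, .2)), 50, 9)
  uvtR <- mkUvt(gH, gL)
  aR <- allelicAssociation(uvtR, paste0("h", 1:9), paste0("l", 1:9))
  for (i in seq_len(nrow(aR))) {
    expect_equal(aR$chi2[i],
                 chi2Oracle(aR$altHfe[i], aR$altHfe[i] + aR$refHfe[i],
                            aR$altLfe[i], aR$altLfe[i] + aR$refLfe[i]),
                 tolerance = 1e-10)
  }

  # trend statistic agrees with the standard score test
  aT <- allelicAssociation(uvtR, paste0("h", 1:9), paste0("l", 1:9),
                           method = "trend")
  for (i in seq_len(10)) {
    hC <- table(factor(gH[i, ], levels = 0:2))
    lC <- table(factor(gL[i, ], levels = 0:2))
    ref <- suppressWarnings(
      stats::prop.trend.test(as.numeric(hC), as.numeric(hC + lC),
                             score = 0:2))
    expect_equal(aT$chi2[i], unname(ref$statistic), tolerance = 1e-10)
  }
  expect_error(allelicAssociation(uvtR, paste0("h", 1:3),
                                  paste0("h", 2:5)), "disjoint")
})

test_that("tissue overlap counts match brute-force subset enumeration", {
  set.seed(3)
  tis <- c("a", "b", "c", "d", "e")
  pres <- matrix(runif(200 * 5) < 0.5, 200, 5,
                 dimnames = list(paste0("v", 1:200), tis))
  uvt <- new("UniqueVariantTable",
             variants = data.frame(chrom = "1", pos = 1:200, ref = "A",
                                   alt = "T", class = "SNP", maf = 0.25,
                                   callRate = 1),
             presence = pres,
             geno = matrix(1L, 200, 2,
                           dimnames = list(NULL, c("s1", "s2"))))
  ov <- tissueOverlap(uvt)
  expect_equal(ov$inAll, sum(rowSums(pres) == 5))
  for (k in 1:5) {
    combos <- utils::combn(tis, k)
    for (j in seq_len(ncol(combos))) {
      combo <- combos[, j]
      brute <- sum(apply(pres, 1, function(r)
        all(r[combo]) && !any(r[setdiff(tis, combo)])))
      expect_equal(unname(ov$pattern[paste(combo, collapse = "+")]),
                   brute)
    }
  }
  # degenerate patterns
  presAll <- matrix(TRUE, 10, 5, dimnames = list(NULL, tis))
  uvtAll <- new("UniqueVariantTable",
                variants = data.frame(chrom = "1", pos = 1:10, ref = "A",
                                      alt = "T", class = "SNP",
                                      maf = 0.25, callRate = 1),
                presence = presAll,
                geno = matrix(1L, 10, 1, dimnames = list(NULL, "s1")))
  expect_equal(tissueOverlap(uvtAll)$inAll, 10)
})

test_that("aggregateReport sums stages and flags bad counts", {
  one <- data.frame(organ = "x", total = 10, filtered = 5,
                    significant = 2)
  expect_equal(unname(aggregateReport(one[-1])$totals), c(10, 5, 2))
  expect_error(aggregateReport(data.frame(total = -1)), "negative")
})
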