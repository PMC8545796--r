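test_that("readSumstats preserves file order, maps columns, reads gzip", {
  df <- do.call(rbind, lapply(1:5, function(i)
    ssRow(sprintf("rs%d", i), "A", "G", beta = i / 100, pos = 1e6 + i)))
  path <- tempfile(fileext = ".tsv")
  writeSumstats(df, path)
  got <- readSumstats(path)
  expect_equal(got$variant_id, df$variant_id)
  expect_equal(got$beta, df$beta)

  ## renamed columns through a column map, gzip-compressed
  df2 <- df
  names(df2)[names(df2) == "variant_id"] <- "SNP"
  names(df2)[names(df2) == "beta"] <- "b"
  gz <- tempfile(fileext = ".tsv.gz")
  writeSumstats(df2, gz)
  got2 <- readSumstats(gz, column_map = c(variant_id = "SNP", beta = "b"))
  expect_equal(got2$beta, df$beta)

  ## lower-case alleles are upper-cased
  df3 <- df; df3$effect_allele <- "a"; df3$other_allele <- "g"
  writeSumstats(df3, path)
  expect_equal(unique(readSumstats(path)$effect_allele), "A")
})

test_that("readSumstats rejects bad rows itemized and errors on bad files", {
  df <- rbind(ssRow("rs1", "A", "G", 0.1), ssRow("rs2", "A", "G", 0.1),
              ssRow("rs3", "A", "G", 0.1))
  df$se <- c("0.01", "0", "0.02")
  path <- tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(got <- readSumstats(path), "non-positive SE")
  expect_equal(got$variant_id, c("rs1", "rs3"))
  rej <- attr(got, "rejected")
  expect_equal(rej$variant_id, "rs2")
  expect_equal(rej$reason, "non-positive SE")

  ## missing mandatory column is named in the error
  df4 <- df[, setdiff(names(df), "se")]
  write.table(df4, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readSumstats(path), "se")

  ## header-only file
  writeLines("variant_id\tbeta\tse\teffect_allele\tother_allele", path)
  expect_error(readSumstats(path), "no data rows")
})

test_that("the bundled instrument table reads with published values", {
  tab <- table1Instruments()
  expect_equal(nrow(tab), 55L)
  expect_equal(as.integer(table(tab$gene)[c("HMGCR", "NPC1L1", "PCSK9",
                                            "LDLR", "CETP", "APOB")]),
               c(5L, 4L, 11L, 12L, 8L, 15L))
  rs <- tab[tab$variant_id == "rs12916", ]
  expect_equal(rs$beta, -0.073)
  expect_equal(rs$eaf, 0.57)
  expect_equal(rs$effect_allele, "T")
  ## SE recovered from the printed CI
  expect_equal(rs$se, (-0.066 - -0.081) / (2 * 1.96))
})

test_that("harmonize aligns swapped, complemented and mismatched alleles", {
  ex <- ssRow("rs1", "A", "G", -0.05)
  ## swapped alleles: beta negated, eaf complemented
  h <- harmonize(ex, ssRow("rs1", "G", "A", 0.02, eaf = 0.7))
  expect_equal(outcomeBeta(h), -0.02)
  ## strand complement, same orientation: unchanged
  h2 <- harmonize(ex, ssRow("rs1", "T", "C", 0.02))
  expect_equal(outcomeBeta(h2), 0.02)
  ## strand complement plus swap: negated
  h3 <- harmonize(ex, ssRow("rs1", "C", "T", 0.02))
  expect_equal(outcomeBeta(h3), -0.02)
  ## irreconcilable alleles
  h4 <- harmonize(ex, ssRow("rs1", "A", "C", 0.02))
  expect_equal(nVariants(h4), 0L)
  expect_equal(dropLog(h4)$reason, "ALLELE_MISMATCH")
  ## absent from outcome
  h5 <- harmonize(ex, ssRow("rs9", "A", "G", 0.02))
  expect_equal(dropLog(h5)$reason, "MISSING_IN_OUTCOME")
  ## duplicate exposure ids are refused
  expect_error(harmonize(rbind(ex, ex), ssRow("rs1", "A", "G", 0.02)),
               "duplicate")
})

test_that("palindromic variants follow the frequency window and orientation", {
  ## ambiguous window: outcome MAF 0.45
  ex <- ssRow("rs1", "A", "T", -0.05, eaf = 0.45)
  h <- harmonize(ex, ssRow("rs1", "A", "T", 0.02, eaf = 0.45))
  expect_equal(nVariants(h), 0L)
  expect_equal(dropLog(h)$reason, "PALINDROMIC_AMBIGUOUS")
  ## boundary: MAF exactly 0.4 is outside the open window and retained
  ex2 <- ssRow("rs1", "A", "T", -0.05, eaf = 0.4)
  h2 <- harmonize(ex2, ssRow("rs1", "A", "T", 0.02, eaf = 0.4))
  expect_equal(nVariants(h2), 1L)
  expect_equal(outcomeBeta(h2), 0.02)
  ## frequencies on opposite sides of 0.5: strand flip inferred
  ex3 <- ssRow("rs1", "A", "T", -0.05, eaf = 0.2)
  h3 <- harmonize(ex3, ssRow("rs1", "A", "T", 0.02, eaf = 0.8))
  expect_equal(outcomeBeta(h3), -0.02)
  ## both frequencies missing: conservative drop
  ex4 <- ssRow("rs1", "A", "T", -0.05, eaf = NA)
  h4 <- harmonize(ex4, ssRow("rs1", "A", "T", 0.02, eaf = NA))
  expect_equal(dropLog(h4)$reason, "PALINDROMIC_AMBIGUOUS")
  ## G/C pair handled identically
  ex5 <- ssRow("rs1", "G", "C", -0.05, eaf = 0.45)
  h5 <- harmonize(ex5, ssRow("rs1", "C", "G", 0.02, eaf = 0.55))
  expect_equal(dropLog(h5)$reason, "PALINDROMIC_AMBIGUOUS")
})

test_that("proxy substitution retains the index variant and is logged", {
  ex <- ssRow("rs1", "A", "G", -0.05)
  outcome <- ssRow("rs99", "A", "G", 0.03)
  proxies <- data.frame(index_id = "rs1", proxy_id = "rs99",
                        effect_allele = "A", other_allele = "G",
                        stringsAsFactors = FALSE)
  h <- harmonize(ex, outcome, proxy_table = proxies)
  expect_equal(variantIds(h), "rs1")
  expect_equal(outcomeBeta(h), 0.03)
  expect_true("PROXY_SUBSTITUTED" %in% dropLog(h)$reason)
  ## proxy with swapped allele coding flips the sign
  proxies2 <- data.frame(index_id = "rs1", proxy_id = "rs99",
                         effect_allele = "G", other_allele = "A",
                         stringsAsFactors = FALSE)
  h2 <- harmonize(ex, outcome, proxy_table = proxies2)
  expect_equal(outcomeBeta(h2), -0.03)
  ## proxy pointing nowhere degrades to MISSING_IN_OUTCOME
  proxies3 <- data.frame(index_id = "rs1", proxy_id = "rs404",
                         stringsAsFactors = FALSE)
  h3 <- harmonize(ex, outcome, proxy_table = proxies3)
  expect_equal(dropLog(h3)$reason, "MISSING_IN_OUTCOME")
})

test_that("PCSK9 against an outcome lacking the three footnoted SNPs keeps 8", {
  pcsk9 <- table1Instruments("PCSK9")
  outcome <- pcsk9[pcsk9$rcc_available, ]
  outcome$beta <- 0.01
  outcome$se <- 0.05
  h <- harmonize(pcsk9, outcome)
  expect_equal(nVariants(h), 8L)
  missing <- dropLog(h)$variant_id[dropLog(h)$reason == "MISSING_IN_OUTCOME"]
  expect_setequal(missing, c("rs11591147", "rs12067569", "rs11583974"))
})

test_that("harmonization is idempotent, sign-consistent and conserving", {
  for (seed in 1:5) {
    sim <- simulateTwoSample(simulationConfig(
      k = 25, seed = seed, palindromic_fraction = 0.3,
      maf_range = c(0.05, 0.5)))
    h <- harmonize(sim$exposure, sim$outcome)
    ## conservation: retained + dropped = input
    dropped <- dropLog(h)
    dropped <- dropped$variant_id[dropped$reason != "PROXY_SUBSTITUTED"]
    expect_setequal(c(variantIds(h), dropped), sim$exposure$variant_id)
    expect_equal(length(variantIds(h)) + length(dropped),
                 nrow(sim$exposure))

    ## idempotence: re-harmonizing the aligned pair changes nothing
    keep <- match(variantIds(h), sim$exposure$variant_id)
    ex2 <- sim$exposure[keep, ]
    out2 <- ex2
    out2$beta <- outcomeBeta(h); out2$se <- outcomeSE(h)
    h2 <- harmonize(ex2, out2)
    expect_equal(nrow(dropLog(h2)), 0L)
    expect_equal(outcomeBeta(h2), outcomeBeta(h))

    ## sign consistency: flipping every outcome record's orientation leaves
    ## retained bx * by products unchanged
    flipped <- sim$outcome
    flipped$effect_allele <- sim$outcome$other_allele
    flipped$other_allele <- sim$outcome$effect_allele
    flipped$beta <- -sim$outcome$beta
    flipped$eaf <- 1 - sim$outcome$eaf
    h3 <- harmonize(sim$exposure, flipped)
    expect_equal(variantIds(h3), variantIds(h))
    expect_equal(exposureBeta(h3) * outcomeBeta(h3),
                 exposureBeta(h) * outcomeBeta(h))
  }
})

test_that("LD matrices round-trip through the plain-text format", {
  rho <- randomRho(4, seed = 11)
  ids <- paste0("rs", 1:4)
  ld <- ldMatrix(rho, ids)
  path <- tempfile(fileext = ".ld")
  writeLDMatrix(ld, path)
  back <- readLDMatrix(path)
  expect_equal(variantIds(back), ids)
  expect_equal(unname(ldRho(back)), unname(ldRho(ld)), tolerance = 1e-12)
  ## alignment subsets and reorders
  sub <- alignLD(ld, c("rs3", "rs1"))
  expect_equal(ldRho(sub)["rs3", "rs1"], rho[3, 1])
  expect_error(alignLD(ld, "rs9"), "rs9")
})
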