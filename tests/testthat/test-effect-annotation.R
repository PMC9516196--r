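test_that("a gained stop and a Pro->Ser substitution are called as in a homeobox gene", {
  # 300-codon gene: codon 276 = TGG (Trp), codon 286 = CCA (Pro), with a
  # homeodomain spanning aa 260-320
  codons <- rep("GCT", 300)
  codons[276] <- "TGG"
  codons[286] <- "CCA"
  cds_seq <- paste(codons, collapse = "")
  ref <- Biostrings::DNAStringSet(paste0("AAAA", cds_seq, "AAAA"))
  names(ref) <- "chr07"
  model <- gene_model("OSH15like", "chr07", "+",
                      data.frame(start = 5, end = 4 + 900),
                      domains = data.frame(name = "homeodomain",
                                           aa_start = 260, aa_end = 320))

  # G-to-A at the third base of codon 276: TGG -> TGA, premature stop
  pos_w276 <- 4 + (276 - 1) * 3 + 3
  stop_call <- annotate_variant(
    variant_records("chr07", pos_w276, "G", "A", 10, 20),
    list(model), ref)
  expect_equal(stop_call$category, "nonsense")
  expect_equal(stop_call$codon_number, 276)
  expect_equal(stop_call$ref_aa, "W")
  expect_equal(stop_call$alt_aa, "*")
  expect_equal(stop_call$domain_hit, "homeodomain")

  # C-to-T at the first base of codon 286: CCA -> TCA, P -> S
  pos_p286 <- 4 + (286 - 1) * 3 + 1
  ps_call <- annotate_variant(
    variant_records("chr07", pos_p286, "C", "T", 10, 20),
    list(model), ref)
  expect_equal(ps_call$category, "missense")
  expect_equal(ps_call$ref_aa, "P")
  expect_equal(ps_call$alt_aa, "S")
  expect_equal(ps_call$codon_number, 286)
  expect_equal(ps_call$domain_hit, "homeodomain")

  # wobble-position change GCT -> GCC stays Ala
  pos_wobble <- 4 + 3
  syn <- annotate_variant(
    variant_records("chr07", pos_wobble, "T", "C", 10, 20),
    list(model), ref)
  expect_equal(syn$category, "synonymous")
})

test_that("minus-strand annotation mirrors the plus-strand construct", {
  for (codon in c("TGG", "CCA", "GAT", "TTA")) {
    plus <- codon_fixture(codon, "+")
    minus <- codon_fixture(codon, "-")
    for (offset in 1:3) {
      ref_base_plus <- substr(codon, offset, offset)
      for (alt_plus in setdiff(c("A", "C", "G", "T"), ref_base_plus)) {
        call_plus <- annotate_variant(
          variant_records("chrT", plus$codon_pos[offset],
                          ref_base_plus, alt_plus, 5, 10),
          list(plus$model), plus$reference)
        comp <- function(b) chartr("ACGT", "TGCA", b)
        call_minus <- annotate_variant(
          variant_records("chrT", minus$codon_pos[offset],
                          comp(ref_base_plus), comp(alt_plus), 5, 10),
          list(minus$model), minus$reference)
        expect_equal(call_minus$category, call_plus$category)
        expect_equal(call_minus$alt_codon, call_plus$alt_codon)
        expect_equal(call_minus$codon_number, call_plus$codon_number)
      }
    }
  }
})

test_that("CDS coordinate mapping round-trips on spliced models of both strands", {
  cds <- data.frame(start = c(11, 31, 61), end = c(19, 45, 72))  # 9+15+12=36
  for (strand in c("+", "-")) {
    m <- gene_model("g", "chr1", strand, cds)
    for (cp in 1:36) {
      gp <- mutmapr:::cds_to_genomic(m, cp)
      expect_equal(mutmapr:::genomic_to_cds(m, gp), cp)
    }
  }
})

test_that("splice-adjacent, noncoding and model validation behave as specified", {
  seq <- paste(rep("ACGT", 50), collapse = "")
  ref <- Biostrings::DNAStringSet(seq)
  names(ref) <- "chr1"
  cds <- data.frame(start = c(11, 31), end = c(19, 45))  # 9 + 15 = 24
  m <- gene_model("g", "chr1", "+", cds)
  base <- function(p) as.character(Biostrings::subseq(ref[["chr1"]], p, p))
  alt_for <- function(p) setdiff(c("A", "C", "G", "T"), base(p))[1]
  # within 2 bp of the donor side of the internal junction
  sa <- annotate_variant(variant_records("chr1", 20, base(20), alt_for(20),
                                         5, 10), list(m), ref)
  expect_equal(sa$category, "splice-adjacent")
  sa2 <- annotate_variant(variant_records("chr1", 29, base(29), alt_for(29),
                                          5, 10), list(m), ref)
  expect_equal(sa2$category, "splice-adjacent")
  # deeper intronic and fully intergenic positions are noncoding
  nc <- annotate_variant(variant_records("chr1", 25, base(25), alt_for(25),
                                         5, 10), list(m), ref)
  expect_equal(nc$category, "noncoding")
  out <- annotate_variant(variant_records("chr1", 100, base(100),
                                          alt_for(100), 5, 10),
                          list(m), ref)
  expect_equal(out$category, "noncoding")

  # every CDS substitution is classified (partition invariant)
  for (p in c(11:19, 31:45)) {
    call <- annotate_variant(variant_records("chr1", p, base(p), alt_for(p),
                                             5, 10), list(m), ref)
    expect_true(call$category %in% c("synonymous", "missense", "nonsense"))
  }

  expect_error(gene_model("bad", "chr1", "+",
                          data.frame(start = 1, end = 4)),
               class = "mutmapr_model_error")
  expect_error(
    annotate_variant(variant_records("chr1", 11,
                                     setdiff(c("A", "C", "G", "T"),
                                             base(11))[1], base(11), 5, 10),
                     list(m), ref),
    class = "mutmapr_integrity_error")
})

test_that("domain lookup uses inclusive amino-acid bounds", {
  m <- gene_model("g", "chr1", "+", data.frame(start = 1, end = 300),
                  domains = data.frame(name = c("KNOX1", "HD"),
                                       aa_start = c(50, 80),
                                       aa_end = c(79, 95)))
  call <- mutmapr:::effect_call_row("g", "missense", codon_number = 50)
  expect_equal(domain_overlap(call, m)$domain_hit, "KNOX1")
  call$codon_number <- 95
  expect_equal(domain_overlap(call, m)$domain_hit, "HD")
  call$codon_number <- 10
  expect_true(is.na(domain_overlap(call, m)$domain_hit))
})
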