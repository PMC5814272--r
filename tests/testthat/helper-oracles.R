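# Independent brute-force oracles and tiny fixture builders used across
# the suite. These deliberately avoid the package's own code paths.

# Full running-sum enrichment score: walk every rank position.
brute_es <- function(genes, weights, gene_set, exponent = 1) {
  N <- length(genes)
  hit <- genes %in% gene_set
  nh <- sum(hit)
  stopifnot(nh >= 1)
  if (nh == N) return(1)
  w <- abs(weights)^exponent
  sw <- sum(w[hit])
  r <- numeric(N)
  run <- 0
  for (i in seq_len(N)) {
    run <- run + if (hit[i]) {
      if (sw > 0) w[i] / sw else 1 / nh
    } else {
      -1 / (N - nh)
    }
    r[i] <- run
  }
  pos <- max(r)
  neg <- min(r, 0)
  # same positive-on-tie rule (with fp tolerance) as the implementation
  if (pos >= -neg - 1e-9) pos else neg
}

# Brute-force k-window enumeration covering position p.
brute_windows <- function(L, p, k) {
  starts <- integer(0)
  for (s in seq_len(max(L - k + 1L, 0L))) {
    if (s <= p && p <= s + k - 1L) starts <- c(starts, s)
  }
  starts
}

# Minimal MAF writer for literal test tables.
write_tiny_maf <- function(rows, path = tempfile(fileext = ".maf")) {
  header <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "Chromosome",
              "Start_Position", "Reference_Allele", "Tumor_Seq_Allele2",
              "Variant_Classification", "HGVSp_Short", "Transcript_ID")
  lines <- c(paste(header, collapse = "\t"),
             vapply(rows, paste, "", collapse = "\t"))
  writeLines(lines, path)
  path
}

maf_row <- function(sample, gene, class, pc = "", ref = "C", alt = "A",
                    pos = 1000, chrom = "1", tx = "") {
  c(gene, sample, chrom, pos, ref, alt, class, pc, tx)
}

# Small deterministic mutation data frame builder (already-parsed shape).
mut_df <- function(sample_id, hugo_symbol, variant_classification,
                   protein_change = "", ref_allele = "C", alt_allele = "A") {
  n <- max(lengths(list(sample_id, hugo_symbol, variant_classification)))
  data.frame(sample_id = rep_len(sample_id, n),
             hugo_symbol = rep_len(hugo_symbol, n),
             chrom = "1", pos = 1000L,
             ref_allele = rep_len(ref_allele, n),
             alt_allele = rep_len(alt_allele, n),
             variant_classification = rep_len(variant_classification, n),
             protein_change = rep_len(protein_change, n),
             transcript_id = "",
             is_silent = rep_len(variant_classification, n) == "silent",
             stringsAsFactors = FALSE)
}
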