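# Export/import of simulated samples: VCFv4.2 (diploid GT, optionally phased
# with a PS phase-set tag), truth-haplotype FASTA (two records per individual
# per contig) and a per-site TSV. Reading goes through vcfR / ape so the files
# round-trip losslessly through standard tooling.

.NUC <- c("A", "C", "G", "T")

#' Write a simulated sample to VCF, FASTA and TSV files
#'
#' Emits `<prefix>.vcf` (VCFv4.2; phased genotypes use `|` separators and a
#' `PS` phase-set tag equal to the first site position of the contig),
#' `<prefix>_haplotypes.fa` (two records per individual per contig, the
#' concatenated alleles at that contig's SNP positions) and
#' `<prefix>_sites.tsv`. Unphased export (`phased = FALSE`) uses `/`
#' separators, sorts each genotype's alleles and drops the `PS` tag.
#'
#' @param sample a `sample_set`.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @param phased write phased genotypes (default: the sample's phasing flag).
#' @return Invisibly, the paths of the written files.
#' @seealso [read_sample_vcf()], [read_haplotype_fasta()]
#' @export
write_sample <- function(sample, dir, prefix = "sample",
                         phased = sample$phased) {
  stopifnot(inherits(sample, "sample_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  vcf <- file.path(dir, paste0(prefix, ".vcf"))
  fa <- file.path(dir, paste0(prefix, "_haplotypes.fa"))
  tsv <- file.path(dir, paste0(prefix, "_sites.tsv"))

  n <- length(sample$individuals)
  s <- n_sites(sample)
  header <- c("##fileformat=VCFv4.2",
              "##source=clonescan",
              sprintf("##contig=<ID=%s,length=%d>",
                      sprintf("ctg%02d", seq_len(sample$config$n_contigs)),
                      sample$contig_length),
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  if (phased)
    header <- c(header,
                "##FORMAT=<ID=PS,Number=1,Type=Integer,Description=\"Phase set\">")
  header <- c(header,
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", sample$individuals), collapse = "\t"))

  body <- character(s)
  if (s > 0) {
    ps <- stats::ave(sample$pos, sample$contig, FUN = min)
    for (j in seq_len(s)) {
      obs <- sort(unique(c(sample$hap1[j, ], sample$hap2[j, ])))
      ref_code <- sample$anc[j]
      if (!ref_code %in% obs) ref_code <- obs[1L]
      alt_codes <- setdiff(obs, ref_code)
      amap <- integer(4L)
      amap[c(ref_code, alt_codes) + 1L] <- seq_along(c(ref_code, alt_codes)) - 1L
      g1 <- amap[sample$hap1[j, ] + 1L]
      g2 <- amap[sample$hap2[j, ] + 1L]
      gt <- if (phased) {
        paste0(g1, "|", g2, ":", ps[j])
      } else {
        paste0(pmin(g1, g2), "/", pmax(g1, g2))
      }
      body[j] <- paste(c(sample$contig[j], sample$pos[j], ".",
                         .NUC[ref_code + 1L],
                         paste(.NUC[alt_codes + 1L], collapse = ","),
                         ".", "PASS", ".",
                         if (phased) "GT:PS" else "GT", gt),
                       collapse = "\t")
    }
  }
  writeLines(c(header, body), vcf)

  fa_lines <- character(0)
  for (ctg in unique(sample$contig)) {
    idx <- which(sample$contig == ctg)
    for (i in seq_len(n)) {
      fa_lines <- c(fa_lines,
                    sprintf(">%s_h1_%s", sample$individuals[i], ctg),
                    paste(.NUC[sample$hap1[idx, i] + 1L], collapse = ""),
                    sprintf(">%s_h2_%s", sample$individuals[i], ctg),
                    paste(.NUC[sample$hap2[idx, i] + 1L], collapse = ""))
    }
  }
  writeLines(fa_lines, fa)

  sites <- data.frame(contig = sample$contig, pos = sample$pos,
                      gpos = sample$gpos,
                      ref = .NUC[sample$anc + 1L],
                      effect = sample$eff)
  write.table(sites, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(vcf = vcf, fasta = fa, sites = tsv))
}

#' Read a (phased) VCF back into a `sample_set`
#'
#' Parses a diploid VCF with `GT` (and optionally `PS`) fields via
#' \pkg{vcfR}. Allele codes are nucleotide codes (A=0, C=1, G=2, T=3). For
#' unphased records the two alleles of a genotype are stored in sorted order,
#' so genotypes (but not haplotype phase) round-trip.
#'
#' @param path VCF file path.
#' @param genome_length,n_contigs coordinate system of the source sample;
#'   defaults recover them from the contig header lines.
#' @return A `sample_set`; `$phased` reflects the GT separators and `$ps`
#'   holds the phase-set matrix (sites x individuals) when present.
#' @export
read_sample_vcf <- function(path, genome_length = NULL, n_contigs = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix)))
    fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  meta <- v@meta
  ctg <- regmatches(meta, regexec("##contig=<ID=([^,>]+),length=([0-9]+)", meta))
  ctg <- ctg[lengths(ctg) == 3L]
  if (is.null(n_contigs)) n_contigs <- length(ctg)
  if (is.null(genome_length))
    genome_length <- sum(as.numeric(vapply(ctg, `[`, "", 3L)))
  clen <- ceiling(genome_length / n_contigs)

  inds <- colnames(v@gt)[-1L]
  s <- nrow(fix)
  n <- length(inds)
  gt <- if (s > 0) vcfR::extract.gt(v, element = "GT") else
    matrix(character(0), 0L, n)
  phased <- s == 0L || all(grepl("|", gt, fixed = TRUE))
  h1 <- h2 <- matrix(0L, nrow = s, ncol = n)
  anc <- integer(s)
  pos <- as.integer(fix[, "POS"])
  contig_idx <- as.integer(sub("ctg", "", fix[, "CHROM"]))
  gpos <- (contig_idx - 1L) * as.integer(clen) + pos
  if (s > 0) {
    a1 <- sub("[|/].*", "", gt)
    a2 <- sub(".*[|/]", "", gt)
    for (j in seq_len(s)) {
      alleles <- c(fix[j, "REF"], strsplit(fix[j, "ALT"], ",")[[1L]])
      codes <- match(alleles, .NUC) - 1L
      anc[j] <- codes[1L]
      h1[j, ] <- codes[as.integer(a1[j, ]) + 1L]
      h2[j, ] <- codes[as.integer(a2[j, ]) + 1L]
    }
    if (!phased) {
      lo <- pmin(h1, h2)
      hi <- pmax(h1, h2)
      h1 <- lo
      h2 <- hi
    }
  }
  cfg <- sim_config(pop_size = max(2L, n), genome_length = genome_length,
                    n_generations = 0L, sample_size = min(n, max(2L, n)),
                    n_contigs = n_contigs)
  out <- .make_sample(h1, h2, gpos, anc, rep(0, s), cfg, 0L,
                      individuals = inds)
  out$phased <- phased
  if (phased && s > 0) {
    psm <- vcfR::extract.gt(v, element = "PS")
    if (!all(is.na(psm))) out$ps <- matrix(as.integer(psm), nrow = s)
  }
  out
}

#' Read truth-haplotype FASTA written by [write_sample()]
#'
#' @param path FASTA file path.
#' @return A named list of character matrices (one per contig, rows =
#'   haplotype records named `IND_h1`/`IND_h2`, columns = SNP positions),
#'   with alleles coded 0-3.
#' @export
read_haplotype_fasta <- function(path) {
  seqs <- ape::read.FASTA(path)
  chars <- lapply(as.character(seqs), function(x) {
    match(toupper(x), .NUC) - 1L
  })
  nm <- names(seqs)
  ctg <- sub(".*_(ctg[0-9]+)$", "\\1", nm)
  rec <- sub("_(ctg[0-9]+)$", "", nm)
  out <- lapply(split(seq_along(nm), ctg), function(idx) {
    m <- do.call(rbind, chars[idx])
    rownames(m) <- rec[idx]
    m
  })
  out[order(names(out))]
}
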