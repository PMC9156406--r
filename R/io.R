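# Readers and writers for the pipeline's native formats: PLINK BED/BIM/FAM,
# VCF, and the TSV schemas (eQTL catalog, expression + metadata, GWAS
# summary, phenotypes, gene annotation). Coordinates are 1-based inclusive
# (GRCh37/VCF convention) throughout.

## ---- PLINK BED/BIM/FAM -----------------------------------------------------
## SNP-major BED v1: magic 0x6c 0x1b 0x01, then ceiling(n/4) bytes per SNP,
## two bits per individual (00 hom A1, 10 het, 11 hom A2, 01 missing). The
## dosage convention here counts allele1 (= A1).

#' Write genotypes as a PLINK BED/BIM/FAM file set
#'
#' The BIM's A1 column is the dosage-counted allele (`allele1` of the
#' variant table); dosages 2/1/0 map to hom-A1/het/hom-A2.
#'
#' @param genotypes A `"coex_genotypes"` object.
#' @param prefix Path prefix; `<prefix>.bed`, `.bim`, `.fam` are written.
#' @return The prefix, invisibly.
#' @export
write_plink <- function(genotypes, prefix) {
  dos <- genotypes$dosage
  v <- genotypes$variants
  n <- nrow(dos)
  fam <- data.frame(fid = rownames(dos), iid = rownames(dos),
                    pat = 0, mat = 0, sex = 0, pheno = -9)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  bim <- data.frame(chrom = v$chrom, id = v$variant_id,
                    cm = numeric(nrow(v)), pos = v$pos,
                    a1 = v$allele1, a2 = v$allele2)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  ## 2-bit codes indexed by dosage of A1: 0 -> 11 (3), 1 -> 10 (2), 2 -> 00 (0)
  code_of <- c(`0` = 3L, `1` = 2L, `2` = 0L)
  bytes_per_snp <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  pad <- bytes_per_snp * 4 - n
  shift <- c(1L, 4L, 16L, 64L)
  for (j in seq_len(ncol(dos))) {
    d <- dos[, j]
    codes <- ifelse(is.na(d), 1L, code_of[as.character(d)])
    codes <- c(codes, rep(0L, pad))
    m <- matrix(codes, nrow = 4)
    writeBin(as.raw(colSums(m * shift)), con)
  }
  invisible(prefix)
}

#' Read a PLINK BED/BIM/FAM file set
#'
#' @param prefix Path prefix of the `.bed`/`.bim`/`.fam` trio.
#' @return A `"coex_genotypes"` object whose dosage counts the BIM A1
#'   allele (`allele1`).
#' @export
read_plink <- function(prefix) {
  for (ext in c(".bed", ".bim", ".fam")) {
    if (!file.exists(paste0(prefix, ext))) {
      stop("missing companion file: ", paste0(prefix, ext), call. = FALSE)
    }
  }
  fam <- utils::read.table(paste0(prefix, ".fam"), stringsAsFactors = FALSE)
  bim <- if (file.size(paste0(prefix, ".bim")) == 0) {
    data.frame(chrom = character(), variant_id = character(), cm = numeric(),
               pos = integer(), allele1 = character(), allele2 = character(),
               stringsAsFactors = FALSE)
  } else {
    utils::read.table(paste0(prefix, ".bim"), stringsAsFactors = FALSE,
                      colClasses = c("character", "character", "numeric",
                                     "integer", "character", "character"))
  }
  names(bim) <- c("chrom", "variant_id", "cm", "pos", "allele1", "allele2")
  n <- nrow(fam)
  m <- nrow(bim)
  raw <- readBin(paste0(prefix, ".bed"), "raw",
                 n = 3 + ceiling(n / 4) * max(m, 1))
  if (length(raw) < 3 || raw[1] != 0x6c || raw[2] != 0x1b) {
    stop("not a PLINK BED file (bad magic bytes at offset 0)", call. = FALSE)
  }
  if (raw[3] != 0x01) {
    stop("only SNP-major BED supported (mode byte at offset 2)", call. = FALSE)
  }
  bytes_per_snp <- ceiling(n / 4)
  if (length(raw) - 3 < bytes_per_snp * m) {
    stop(sprintf("truncated BED: expected %d data bytes, found %d (offset %d)",
                 bytes_per_snp * m, length(raw) - 3, length(raw)), call. = FALSE)
  }
  body <- raw[-(1:3)]
  dosage_of <- c(2, NA, 1, 0)              # indexed by 2-bit code + 1
  dosage <- matrix(NA_real_, n, m)
  if (m > 0) {
    ints <- as.integer(body[seq_len(bytes_per_snp * m)])
    codes <- rbind(ints %% 4L, (ints %/% 4L) %% 4L,
                   (ints %/% 16L) %% 4L, (ints %/% 64L) %% 4L)
    dim(codes) <- c(bytes_per_snp * 4L, m)
    dosage <- matrix(dosage_of[codes[seq_len(n), , drop = FALSE] + 1L], n, m)
  }
  rownames(dosage) <- fam[[2]]
  colnames(dosage) <- bim$variant_id
  genotype_matrix(dosage, bim[c("variant_id", "chrom", "pos",
                                "allele1", "allele2")])
}

## ---- VCF -------------------------------------------------------------------

#' Write genotypes as an uncompressed VCF
#'
#' REF is the variant table's `allele2` and ALT its `allele1` (the counted
#' allele), so that ALT-allele counts reproduce the dosage matrix. Hard
#' dosages are written as GT (`0/0`, `0/1`, `1/1`, `./.`).
#'
#' @param genotypes A `"coex_genotypes"` object.
#' @param path Output `.vcf` path.
#' @return The path, invisibly.
#' @export
write_vcf <- function(genotypes, path) {
  dos <- genotypes$dosage
  v <- genotypes$variants
  gt_of <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(dos)), collapse = "\t"))
  body <- vapply(seq_len(ncol(dos)), function(j) {
    d <- dos[, j]
    gt <- ifelse(is.na(d), "./.", gt_of[as.character(d)])
    paste(c(v$chrom[j], v$pos[j], v$variant_id[j], v$allele2[j], v$allele1[j],
            ".", "PASS", ".", "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read genotypes from a VCF
#'
#' Dosages count the ALT allele, derived from the GT field (or the DS field
#' when present and `prefer_ds = TRUE`).
#'
#' @param path VCF path (plain or gzipped; parsed with \pkg{vcfR}).
#' @param prefer_ds Use the DS (dosage) FORMAT field when available.
#' @return A `"coex_genotypes"` object (`allele1` = ALT = counted allele,
#'   `allele2` = REF).
#' @export
read_vcf <- function(path, prefer_ds = TRUE) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  has_ds <- prefer_ds && "DS" %in%
    unlist(strsplit(unique(vcf@gt[, "FORMAT"]), ":"))
  if (nrow(fix) == 0) {
    samples <- setdiff(colnames(vcf@gt), "FORMAT")
    dosage <- matrix(NA_real_, length(samples), 0,
                     dimnames = list(samples, NULL))
    variants <- data.frame(variant_id = character(), chrom = character(),
                           pos = integer(), allele1 = character(),
                           allele2 = character(), stringsAsFactors = FALSE)
    return(genotype_matrix(dosage, variants))
  }
  if (has_ds) {
    ds <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
    dosage <- t(ds)
  } else {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    count_alt <- function(g) {
      ifelse(is.na(g) | g %in% c("./.", "."), NA_real_,
             vapply(strsplit(gsub("\\|", "/", g), "/"),
                    function(a) sum(a == "1"), numeric(1)))
    }
    dosage <- t(apply(gt, 2, count_alt))
    if (nrow(fix) == 1) dosage <- t(dosage)   # apply() drops to a vector
  }
  variants <- data.frame(variant_id = fix$ID, chrom = fix$CHROM,
                         pos = as.integer(fix$POS), allele1 = fix$ALT,
                         allele2 = fix$REF, stringsAsFactors = FALSE)
  colnames(dosage) <- variants$variant_id
  genotype_matrix(dosage, variants)
}

#' Read genotypes in either supported format
#'
#' @param path PLINK prefix (for `format = "plink-bed"`) or VCF path.
#' @param format `"plink-bed"` or `"vcf"`.
#' @return A `"coex_genotypes"` object.
#' @export
read_genotypes <- function(path, format = c("plink-bed", "vcf")) {
  format <- match.arg(format)
  switch(format, `plink-bed` = read_plink(path), vcf = read_vcf(path))
}

## ---- TSV schemas -----------------------------------------------------------

.schemas <- list(
  eqtl = list(
    required = c("gene_id", "variant_id", "chrom", "pos", "effect_allele",
                 "other_allele", "slope", "pval_nominal"),
    numeric = c("pos", "slope", "pval_nominal")),
  annotation = list(
    required = c("gene_id", "chrom", "start", "end"),
    numeric = c("start", "end")),
  gwas = list(
    required = c("variant_id", "effect_allele", "other_allele", "beta", "p"),
    numeric = c("beta", "p")),
  expression = list(required = "gene_id", numeric = character()),
  sample_meta = list(
    required = c("sample_id", "region", "stage"), numeric = character()),
  phenotype = list(required = c("individual_id"), numeric = character())
)

.validate_rows <- function(df, schema) {
  reason <- rep(NA_character_, nrow(df))
  if (schema == "eqtl" && nrow(df) > 0) {
    bad <- df$effect_allele == df$other_allele
    reason[bad & is.na(reason)] <- "effect_allele equals other_allele"
    bad <- !is.na(df$pval_nominal) &
      (df$pval_nominal <= 0 | df$pval_nominal > 1)
    reason[bad & is.na(reason)] <- "pval_nominal outside (0, 1]"
  }
  if (schema == "annotation" && nrow(df) > 0) {
    bad <- df$start > df$end
    reason[bad & is.na(reason)] <- "start greater than end"
  }
  if (schema == "gwas" && nrow(df) > 0) {
    bad <- df$effect_allele == df$other_allele
    reason[bad & is.na(reason)] <- "effect_allele equals other_allele"
    bad <- !is.na(df$p) & (df$p <= 0 | df$p > 1)
    reason[bad & is.na(reason)] <- "p outside (0, 1]"
  }
  reason
}

#' Read and validate a pipeline TSV
#'
#' Reads a tab-separated table, checks the mandatory columns of the named
#' schema (order-insensitive; extra columns kept), coerces numeric columns,
#' and rejects rows violating the schema's row invariants into a sidecar
#' attribute rather than failing.
#'
#' @param path TSV path with a header row.
#' @param schema One of `"eqtl"`, `"annotation"`, `"gwas"`,
#'   `"expression"`, `"sample_meta"`, `"phenotype"`.
#' @return Data frame of valid rows with attribute `rejected` (data frame
#'   of invalid rows plus a `reason` column).
#' @export
read_table <- function(path, schema = names(.schemas)) {
  schema <- match.arg(schema)
  sch <- .schemas[[schema]]
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  missing <- setdiff(sch$required, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s table %s is missing mandatory column(s): %s",
                 schema, path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  for (col in sch$numeric) df[[col]] <- as.numeric(df[[col]])
  reason <- .validate_rows(df, schema)
  rejected <- df[!is.na(reason), , drop = FALSE]
  if (nrow(rejected) > 0) rejected$reason <- reason[!is.na(reason)]
  out <- df[is.na(reason), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, rejected = rejected)
}

#' Write a pipeline table as TSV
#'
#' @param df Data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an expression matrix and its sample metadata as TSVs
#'
#' @param expr A `"coex_expression"` object.
#' @param expr_path Genes-by-samples TSV (first column `gene_id`).
#' @param meta_path Sample metadata TSV (`sample_id`, `region`, `stage`).
#' @return `expr_path`, invisibly.
#' @export
write_expression <- function(expr, expr_path, meta_path) {
  df <- data.frame(gene_id = rownames(expr$expr), expr$expr,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_table(df, expr_path)
  write_table(expr$samples, meta_path)
  invisible(expr_path)
}

#' Read an expression matrix and its sample metadata
#'
#' @param expr_path,meta_path Paths written by [write_expression()].
#' @return A `"coex_expression"`-like list with `expr` and `samples`.
#' @export
read_expression <- function(expr_path, meta_path) {
  df <- read_table(expr_path, "expression")
  meta <- read_table(meta_path, "sample_meta")
  mat <- as.matrix(df[, setdiff(names(df), "gene_id"), drop = FALSE])
  rownames(mat) <- df$gene_id
  storage.mode(mat) <- "double"
  if (!identical(colnames(mat), meta$sample_id)) {
    mat <- mat[, meta$sample_id, drop = FALSE]
  }
  structure(list(expr = mat, samples = meta), class = "coex_expression")
}
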