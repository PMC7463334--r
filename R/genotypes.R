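#' Genotype matrix container
#'
#' Individuals x biallelic SNPs, coded as alternate-allele dosage 0/1/2 with
#' `NA` for missing, plus individual metadata (id, site, coordinates) and
#' SNP metadata (scaffold, 1-based position, ref/alt alleles).
#'
#' @param geno integer matrix, individuals x SNPs, values in `{0, 1, 2, NA}`.
#' @param ind data frame with at least `id` and `site`.
#' @param snps data frame with `scaffold`, `pos`, `ref`, `alt`.
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, ind, snps) {
  geno <- as.matrix(geno)
  stopifnot(nrow(geno) == nrow(ind), ncol(geno) == nrow(snps),
            all(geno %in% c(0L, 1L, 2L, NA)),
            all(nzchar(as.character(ind$site))))
  colnames(geno) <- sprintf("%s:%d", snps$scaffold, snps$pos)
  rownames(geno) <- ind$id
  structure(list(geno = geno, ind = ind, snps = snps),
            class = "genotype_matrix")
}

#' @exportS3Method base::print
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d individuals x %d SNPs, %d sites, %.1f%% missing\n",
              nrow(x$geno), ncol(x$geno), length(unique(x$ind$site)),
              100 * mean(is.na(x$geno))))
  invisible(x)
}

#' Write genotypes as a minimal VCF
#'
#' Plain-text VCFv4.2 with a single GT FORMAT field; missing genotypes are
#' written as `./.`.
#'
#' @param gm a [genotype_matrix()].
#' @param path output file.
#' @export
write_vcf <- function(gm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=reefscape",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", gm$ind$id), collapse = "\t")), con)
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  for (j in seq_len(ncol(gm$geno))) {
    g <- gm$geno[, j]
    gt <- ifelse(is.na(g), "./.", gt_code[as.character(g)])
    writeLines(paste(c(gm$snps$scaffold[j], gm$snps$pos[j], ".",
                       gm$snps$ref[j], gm$snps$alt[j], ".", "PASS", ".",
                       "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read genotypes from a VCF and a sites table
#'
#' Parses the GT field via vcfR; non-biallelic records are skipped with a
#' message reporting their count.
#'
#' @param vcf_path VCF file (plain or gzipped).
#' @param sites data frame with `id`, `site` and optionally `x`, `y` (or
#'   `lon`, `lat`), matching the VCF sample names.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(vcf_path, sites) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  bi <- vcfR::is.biallelic(v)
  if (any(!bi))
    message(sum(!bi), " non-biallelic record(s) skipped")
  gt <- vcfR::extract.gt(v[bi, ], element = "GT")
  allele_count <- function(x) {
    x[x %in% c(".", "./.", ".|.")] <- NA
    a <- strsplit(gsub("\\|", "/", x), "/")
    vapply(a, function(p) {
      if (anyNA(p) || length(p) != 2 || any(p == ".")) return(NA_integer_)
      sum(as.integer(p))
    }, integer(1))
  }
  geno <- t(apply(gt, 1, allele_count))
  # rows = variants, cols = samples -> transpose to individuals x SNPs
  geno <- t(geno)
  m <- match(rownames(geno), sites$id)
  if (anyNA(m)) stop("sample(s) missing from sites table: ",
                     paste(rownames(geno)[is.na(m)], collapse = ", "))
  fix <- fix[bi, , drop = FALSE]
  genotype_matrix(geno, sites[m, , drop = FALSE],
                  data.frame(scaffold = fix$CHROM,
                             pos = as.integer(fix$POS),
                             ref = fix$REF, alt = fix$ALT))
}

subset_gm <- function(gm, ind = NULL, snp = NULL) {
  if (is.null(ind)) ind <- seq_len(nrow(gm$geno))
  if (is.null(snp)) snp <- seq_len(ncol(gm$geno))
  out <- genotype_matrix(gm$geno[ind, snp, drop = FALSE],
                         gm$ind[ind, , drop = FALSE],
                         gm$snps[snp, , drop = FALSE])
  attr(out, "truth") <- attr(gm, "truth")
  out
}

#' Quality filtering of SNPs and individuals
#'
#' Individuals with missing rate `>= miss` are removed first; then SNPs are
#' dropped when their minor allele frequency is `<= maf`, when their most
#' frequent genotype class has frequency `>= major_geno`, or when their
#' missing rate is `>= miss` (i.e. survivors satisfy MAF > maf, major
#' genotype < major_geno, missing < miss). A step-by-step count report is
#' attached as the `"filter_report"` attribute.
#'
#' @param gm a [genotype_matrix()].
#' @param maf minor-allele-frequency threshold.
#' @param major_geno major-genotype-frequency threshold.
#' @param miss missing-rate threshold (individuals and SNPs).
#' @return the filtered [genotype_matrix()].
#' @export
filter_snps <- function(gm, maf = 0.05, major_geno = 0.95, miss = 0.1) {
  ind_miss <- rowMeans(is.na(gm$geno))
  keep_ind <- ind_miss < miss
  g <- gm$geno[keep_ind, , drop = FALSE]
  snp_miss <- colMeans(is.na(g))
  p <- colMeans(g, na.rm = TRUE) / 2
  mafv <- pmin(p, 1 - p)
  mgf <- apply(g, 2, function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(1)
    max(tabulate(x + 1L, 3L)) / length(x)
  })
  keep_snp <- !is.na(mafv) & mafv > maf & mgf < major_geno & snp_miss < miss
  if (!any(keep_ind) || !any(keep_snp))
    stop("filtering removed everything")
  out <- subset_gm(gm, which(keep_ind), which(keep_snp))
  attr(out, "filter_report") <- data.frame(
    step = c("input_ind", "ind_missing_removed", "input_snp",
             "snp_maf_removed", "snp_major_geno_removed",
             "snp_missing_removed", "snp_kept"),
    n = c(nrow(gm$geno), sum(!keep_ind), ncol(gm$geno),
          sum(!is.na(mafv) & mafv <= maf),
          sum(mgf >= major_geno), sum(snp_miss >= miss), sum(keep_snp)))
  out
}

#' Greedy linkage-disequilibrium pruning
#'
#' Walks SNPs in (scaffold, position) order; a SNP is kept unless its
#' squared Pearson correlation (pairwise-complete dosages) with an
#' already-kept SNP within the trailing window exceeds `r2`. First kept
#' wins.
#'
#' @param gm a [genotype_matrix()].
#' @param r2 squared-correlation threshold.
#' @param window_snps window width in SNPs (within the same scaffold).
#' @return the pruned [genotype_matrix()].
#' @export
ld_prune <- function(gm, r2 = 0.3, window_snps = 50) {
  ord <- order(gm$snps$scaffold, gm$snps$pos)
  g <- gm$geno[, ord, drop = FALSE]
  scf <- gm$snps$scaffold[ord]
  kept <- integer(0)
  for (j in seq_len(ncol(g))) {
    win <- kept[scf[kept] == scf[j] & kept >= j - window_snps]
    drop <- FALSE
    for (k in rev(win)) {
      r <- suppressWarnings(stats::cor(g[, j], g[, k],
                                       use = "pairwise.complete.obs"))
      if (!is.na(r) && r^2 > r2) { drop <- TRUE; break }
    }
    if (!drop) kept <- c(kept, j)
  }
  subset_gm(gm, snp = ord[kept])
}

#' Population-structure covariate
#'
#' Default: leading axes of a principal decomposition of the centered
#' dosage matrix (missing entries imputed to the locus mean) — the role the
#' first discriminant function of a DAPC plays as a confounding covariate
#' in association models. An externally computed covariate (e.g. a DAPC
#' axis) can be loaded from CSV instead and is passed through unchanged.
#'
#' @param gm a [genotype_matrix()].
#' @param method `"pca"` or `"file"`.
#' @param k number of axes (pca).
#' @param file CSV with columns `id` and one column per covariate
#'   (method = "file").
#' @return numeric matrix, individuals x k, rownames = individual ids. A
#'   `"zero_variance"` attribute flags degenerate axes.
#' @export
structure_covariate <- function(gm, method = c("pca", "file"), k = 1,
                                file = NULL) {
  method <- match.arg(method)
  if (method == "file") {
    df <- utils::read.csv(file)
    m <- match(gm$ind$id, df$id)
    if (anyNA(m)) stop("covariate file misses individual(s)")
    out <- as.matrix(df[m, setdiff(names(df), "id"), drop = FALSE])
    rownames(out) <- gm$ind$id
    return(out)
  }
  if (k >= nrow(gm$geno)) stop("k must be smaller than the number of individuals")
  g <- gm$geno
  mu <- colMeans(g, na.rm = TRUE)
  for (j in seq_len(ncol(g))) g[is.na(g[, j]), j] <- mu[j]
  g <- sweep(g, 2, mu)
  sv <- svd(g, nu = k, nv = 0)
  ax <- sv$u %*% diag(sv$d[seq_len(k)], k)
  rownames(ax) <- gm$ind$id
  colnames(ax) <- paste0("PC", seq_len(k))
  attr(ax, "zero_variance") <- sv$d[seq_len(k)] < 1e-8 * max(sv$d[1], 1e-300)
  ax
}

# Weir & Cockerham (1984) variance components per locus.
# geno: individuals x loci dosage matrix; pops: factor of populations.
# Returns L x 3 matrix of components a (among populations), b (among
# individuals within populations), c (within individuals).
wc_components <- function(geno, pops) {
  pops <- droplevels(as.factor(pops))
  r <- nlevels(pops)
  L <- ncol(geno)
  nmat <- matrix(0, r, L); pmat <- matrix(NA_real_, r, L)
  hmat <- matrix(NA_real_, r, L)
  for (i in seq_len(r)) {
    g <- geno[pops == levels(pops)[i], , drop = FALSE]
    nmat[i, ] <- colSums(!is.na(g))
    pmat[i, ] <- colMeans(g, na.rm = TRUE) / 2
    hmat[i, ] <- colMeans(g == 1, na.rm = TRUE)
  }
  ok <- colSums(nmat > 0) == r & colSums(nmat) > r  # all pops observed
  nbar <- colSums(nmat) / r
  nc <- (r * nbar - colSums(nmat^2) / (r * nbar)) / (r - 1)
  pbar <- colSums(nmat * pmat) / (r * nbar)
  s2 <- colSums(nmat * sweep(pmat, 2, pbar)^2) / ((r - 1) * nbar)
  hbar <- colSums(nmat * hmat) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r -
       hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  out <- cbind(a = a, b = b, c = cc)
  out[!ok, ] <- NA_real_
  out
}

#' Multi-locus Weir-Cockerham FST
#'
#' Ratio-of-sums estimator: `sum(a) / sum(a + b + c)` over loci with data in
#' every population. Can be negative (estimator property).
#'
#' @param geno dosage matrix.
#' @param pops population factor.
#' @return scalar FST estimate.
#' @export
wc_fst <- function(geno, pops) {
  comp <- wc_components(geno, pops)
  comp <- comp[stats::complete.cases(comp), , drop = FALSE]
  if (!nrow(comp)) stop("no callable loci shared by all populations")
  sum(comp[, "a"]) / sum(comp)
}

#' Pairwise Weir-Cockerham FST between sampling sites
#'
#' Sites with `min_n` or fewer genotyped individuals are excluded (default
#' strict `> 10` rule). For each remaining ordered-lexicographic site pair
#' the multi-locus ratio-of-sums estimator is computed on the two sites'
#' individuals.
#'
#' @param gm a [genotype_matrix()].
#' @param min_n minimum site sample size; sites with `<= min_n` individuals
#'   are dropped.
#' @param clamp if `TRUE`, negative estimates are clamped to 0.
#' @return data frame with `site1`, `site2` (site1 < site2), `fst`, `n1`,
#'   `n2`.
#' @export
pairwise_fst <- function(gm, min_n = 10, clamp = FALSE) {
  tab <- table(gm$ind$site)
  sites <- sort(names(tab)[tab > min_n])
  if (length(sites) < 2) stop("fewer than 2 sites pass the sample-size rule")
  pairs <- utils::combn(sites, 2)
  res <- data.frame(site1 = pairs[1, ], site2 = pairs[2, ],
                    fst = NA_real_, n1 = NA_integer_, n2 = NA_integer_)
  for (i in seq_len(ncol(pairs))) {
    sel <- gm$ind$site %in% pairs[, i]
    res$fst[i] <- wc_fst(gm$geno[sel, , drop = FALSE], gm$ind$site[sel])
    res$n1[i] <- tab[pairs[1, i]]; res$n2[i] <- tab[pairs[2, i]]
  }
  if (clamp) res$fst <- pmax(res$fst, 0)
  res
}

#' Sliding-window FST scan along the genome
#'
#' Per-SNP Weir-Cockerham FST across the given populations, plus
#' non-overlapping window means by scaffold, for flagging candidate
#' high-FST genomic islands.
#'
#' @param gm a [genotype_matrix()].
#' @param pops population assignment per individual (defaults to site).
#' @param window_kb window width in kb.
#' @return list with `snp` (per-SNP data frame: scaffold, pos, fst) and
#'   `window` (scaffold, start, end, n_snps, fst = ratio-of-sums within the
#'   window).
#' @export
fst_scan <- function(gm, pops = gm$ind$site, window_kb = 50) {
  comp <- wc_components(gm$geno, pops)
  snp <- data.frame(scaffold = gm$snps$scaffold, pos = gm$snps$pos,
                    fst = comp[, "a"] / rowSums(comp))
  w <- max(1, window_kb * 1000)
  bin <- floor((gm$snps$pos - 1) / w)
  keyv <- paste(gm$snps$scaffold, bin)
  agg <- function(idx) {
    cc <- comp[idx, , drop = FALSE]
    cc <- cc[stats::complete.cases(cc), , drop = FALSE]
    if (!nrow(cc)) return(NA_real_)
    sum(cc[, "a"]) / sum(cc)
  }
  keys <- unique(keyv)
  win <- do.call(rbind, lapply(keys, function(k) {
    idx <- which(keyv == k)
    data.frame(scaffold = gm$snps$scaffold[idx[1]],
               start = bin[idx[1]] * w + 1, end = (bin[idx[1]] + 1) * w,
               n_snps = length(idx), fst = agg(idx))
  }))
  list(snp = snp, window = win)
}
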