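# Readers, writers, the locus filter and run configuration. The VCF subset
# handled is what the simulator writes and RAD-seq SNP matrices need:
# biallelic records, unphased GT, "./." for missing, one contig per RAD
# locus with nominal positions (no reference genome exists for de novo RAD
# data).

#' Read a genotype matrix
#'
#' @param path VCF (`format = "vcf"`, parsed with vcfR) or TSV
#'   (`format = "tsv"`: rows = individuals, columns = loci, cells 0/1/2/NA,
#'   first column `id`).
#' @param format `"vcf"` or `"tsv"`; guessed from the extension by default.
#' @return A [GenotypeMatrix-class]. Multi-allelic VCF records are dropped
#'   with a warning reporting the count.
#' @export
readGenotypes <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "tsv") {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             check.names = FALSE, stringsAsFactors = FALSE)
    ids <- as.character(tab[[1]])
    m <- as.matrix(tab[, -1, drop = FALSE])
    storage.mode(m) <- "integer"
    rownames(m) <- ids
    return(genotypeMatrix(m))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  multi <- grepl(",", fix[, "ALT"])
  if (any(multi)) {
    warning(sum(multi), " multi-allelic records dropped")
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  code <- function(x) {
    x <- gsub("\\|", "/", x)
    out <- rep(NA_integer_, length(x))
    ok <- !is.na(x) & !x %in% c("./.", ".")
    out[ok] <- vapply(strsplit(x[ok], "/", fixed = TRUE), function(al) {
      if (any(al == ".")) return(NA_integer_)
      sum(al != "0")
    }, integer(1))
    out
  }
  m <- apply(gt, 2, code)
  dimnames(m) <- dimnames(gt)
  m <- t(m)  # individuals x loci
  storage.mode(m) <- "integer"
  locus <- fix[, "ID"]
  locus[is.na(locus) | locus == "."] <-
    paste0(fix[, "CHROM"], "_", fix[, "POS"])[is.na(locus) | locus == "."]
  colnames(m) <- locus
  genotypeMatrix(m, locusData = data.frame(locus = locus,
                                           radLocus = fix[, "CHROM"]))
}

#' Write a genotype matrix as minimal VCF
#'
#' One contig per RAD locus (CHROM = `locusData$radLocus`), nominal 1-based
#' positions, REF `A` / ALT `T`, unphased GT with `./.` for missing.
#'
#' @param g a [GenotypeMatrix-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGenotypesVcf <- function(g, path) {
  gm <- genotypes(g)
  ld <- locusData(g)
  chrom <- if ("radLocus" %in% colnames(ld)) ld$radLocus else ld$locus
  gtcode <- c("0/0", "0/1", "1/1")
  lines <- c("##fileformat=VCFv4.2",
             "##source=coalABC",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", rownames(gm)), collapse = "\t"))
  body <- vapply(seq_len(ncol(gm)), function(l) {
    gt <- ifelse(is.na(gm[, l]), "./.", gtcode[gm[, l] + 1L])
    paste(c(chrom[l], "1", colnames(gm)[l], "A", "T", ".", "PASS", ".",
            "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Write a genotype matrix as TSV
#' @inheritParams writeGenotypesVcf
#' @return `path`, invisibly.
#' @export
writeGenotypesTsv <- function(g, path) {
  gm <- genotypes(g)
  df <- data.frame(id = rownames(gm), gm, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' TSV with at least an `id` column; `group`, `lat`, `lon`, `species` are
#' used when present.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
readSampleSheet <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!"id" %in% colnames(tab)) stop("sample sheet needs an 'id' column")
  tab
}

#' Write per-locus alignments as FASTA
#'
#' One multi-FASTA per locus, `<locus>.fasta`, in `dir`.
#'
#' @param a a [LocusAlignmentSet-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeAlignments <- function(a, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  alns <- alignments(a)
  for (k in seq_along(alns))
    Biostrings::writeXStringSet(alns[[k]],
                                file.path(dir, paste0(names(alns)[k],
                                                      ".fasta")))
  invisible(dir)
}

#' Read per-locus alignments from FASTA files
#' @param dir directory of `.fasta` files (one per locus).
#' @return A [LocusAlignmentSet-class].
#' @export
readAlignments <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.fasta$", full.names = TRUE))
  if (!length(files)) stop("no .fasta files in ", dir)
  alns <- lapply(files, Biostrings::readDNAStringSet)
  names(alns) <- sub("\\.fasta$", "", basename(files))
  locusAlignmentSet(alns)
}

#' Read a STRUCTURE log-likelihood table
#' @param path TSV with columns `K`, `run`, `lnP`.
#' @return data.frame suitable for [evannoDeltaK()].
#' @export
readLnPTable <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!all(c("K", "run", "lnP") %in% colnames(tab)))
    stop("lnP table needs columns K, run, lnP")
  tab
}

#' Filter SNP loci on missingness and one SNP per RAD locus
#'
#' Drops loci whose missing fraction exceeds `maxMissing` (default 0.2),
#' then, within each RAD-locus group (`locusData$radLocus`), retains a
#' single SNP chosen uniformly at random.
#'
#' @param g a [GenotypeMatrix-class].
#' @param maxMissing maximum tolerated per-locus missing fraction.
#' @param oneSnpPerLocus apply the one-random-SNP-per-RAD-locus rule
#'   (requires a `radLocus` column in `locusData`).
#' @param seed optional integer seed for the random SNP choice.
#' @return The filtered [GenotypeMatrix-class].
#' @export
filterLoci <- function(g, maxMissing = 0.2, oneSnpPerLocus = TRUE,
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gm <- genotypes(g)
  ld <- locusData(g)
  keep <- colMeans(is.na(gm)) <= maxMissing
  if (oneSnpPerLocus && "radLocus" %in% colnames(ld)) {
    grp <- ld$radLocus
    for (rl in unique(grp[keep])) {
      idx <- which(keep & grp == rl)
      if (length(idx) > 1)
        keep[setdiff(idx, idx[sample.int(length(idx), 1L)])] <- FALSE
    }
  }
  if (!any(keep)) stop("no loci survive filtering")
  genotypeMatrix(gm[, keep, drop = FALSE], sampleData = sampleData(g),
                 locusData = ld[keep, , drop = FALSE])
}

#' Write a simulated dataset with its provenance sidecar
#'
#' VCF genotypes, per-locus FASTA alignments (if any) and a JSON sidecar
#' recording the truth scenario, sampling design and seed.
#'
#' @param d list from [simulateDataset()].
#' @param dir output directory.
#' @param seed the seed the dataset was generated under (recorded only).
#' @return `dir`, invisibly.
#' @export
writeDataset <- function(d, dir, seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeGenotypesVcf(d$genotypes, file.path(dir, "genotypes.vcf"))
  if (!is.null(d$alignments))
    writeAlignments(d$alignments, file.path(dir, "alignments"))
  tr <- d$truth
  side <- list(scenario = list(kind = tr@kind, Nc = tr@Nc, Nanc = tr@Nanc,
                               Npost = tr@Npost, Texp = tr@Texp,
                               generationTime = tr@generationTime),
               nIndividuals = nIndividuals(d$genotypes),
               nLoci = nLoci(d$genotypes), seed = seed)
  jsonlite::write_json(side, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read or write a run configuration
#'
#' YAML round-trip of the knobs a full run needs: seed, priors, simulation
#' and acceptance counts, filter thresholds.
#'
#' @param path YAML file.
#' @return For `readRunConfig`, a named list with defaults filled in.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(seed = 1L, nSimsPerModel = 10000L, nAccept = 500L,
                   maxMissing = 0.2, priors = defaultPriors())
  out <- utils::modifyList(defaults, cfg)
  if (out$maxMissing < 0 || out$maxMissing >= 1)
    stop("maxMissing must be in [0, 1)")
  out
}

#' @rdname readRunConfig
#' @param config named list as returned by `readRunConfig`.
#' @return For `writeRunConfig`, `path` invisibly.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
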