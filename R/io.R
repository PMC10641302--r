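#' Write a POD as per-locus FASTA files with a manifest
#'
#' One FASTA file per locus (`locus1.fasta`, ...; headers
#' `>sample{i}_allele{j}`) plus a tab-separated `manifest.tsv` with
#' columns `locus`, `length`, `file`.
#'
#' @param pod A `haplotype_dataset`.
#' @param dir Output directory (created if needed).
#' @return The manifest data frame, invisibly.
#' @export
write_pod_fasta <- function(pod, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("locus%d.fasta", seq_along(pod$loci))
  for (l in seq_along(pod$loci)) {
    aln <- pod$loci[[l]]
    bin <- ape::as.DNAbin(tolower(aln))
    ape::write.FASTA(bin, file.path(dir, files[l]))
  }
  manifest <- data.frame(locus = seq_along(pod$loci),
                         length = vapply(pod$loci, ncol, 0L),
                         file = files)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' Read per-locus FASTA alignments as a haplotype dataset
#'
#' Reads either every `*.fasta` file in a directory (or those listed in
#' its `manifest.tsv` when present) or an explicit vector of file paths.
#' All loci must contain the same number of equal-length sequences.
#'
#' @param path Directory or character vector of FASTA files.
#' @return A `haplotype_dataset` (with `NULL` model provenance).
#' @export
read_pod_fasta <- function(path) {
  files <- if (length(path) == 1L && dir.exists(path)) {
    man <- file.path(path, "manifest.tsv")
    if (file.exists(man)) {
      m <- utils::read.delim(man)
      file.path(path, m$file)
    } else {
      list.files(path, pattern = "\\.fa(sta)?$", full.names = TRUE)
    }
  } else path
  if (!length(files)) stop("no FASTA files found")
  loci <- lapply(files, function(f) {
    bin <- ape::read.FASTA(f)
    m <- toupper(as.character(as.matrix(bin)))
    rownames(m) <- labels(bin)
    m
  })
  n <- unique(vapply(loci, nrow, 0L))
  if (length(n) != 1L) stop("loci disagree on the number of sequences")
  comp <- dataset_composition(n, ncol(loci[[1]]), length(loci))
  structure(list(loci = loci, model = NULL, comp = comp, mm = NULL,
                 seed = NULL),
            class = "haplotype_dataset")
}

#' Write segregating-site patterns in ms-style format
#'
#' The conventional coalescent-simulator interchange format: each locus is
#' a `//` block with `segsites:`, a `positions:` line (uniform placeholder
#' positions, as the infinite-sites model carries no physical positions),
#' and one 0/1 row per haplotype.
#'
#' @param patterns A `segregating_patterns` list (from
#'   [simulate_null_replicate()]) or list of 0/1 matrices.
#' @param file Output path or connection.
#' @return `file`, invisibly.
#' @export
write_ms <- function(patterns, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("ms-style output", con)
  for (mat in patterns) {
    writeLines("", con)
    writeLines("//", con)
    S <- ncol(mat)
    writeLines(sprintf("segsites: %d", S), con)
    if (S > 0) {
      pos <- (seq_len(S) - 0.5) / S
      writeLines(paste("positions:", paste(sprintf("%.5f", pos),
                                           collapse = " ")), con)
      writeLines(apply(mat, 1L, paste, collapse = ""), con)
    }
  }
  invisible(file)
}

#' Read ms-style segregating-site patterns
#'
#' @param file Path to a file written by [write_ms()] or an ms-compatible
#'   simulator.
#' @return A `segregating_patterns` list of 0/1 integer matrices.
#' @export
read_ms <- function(file) {
  lines <- readLines(file)
  starts <- which(lines == "//")
  if (!length(starts)) stop("no '//' locus blocks found")
  loci <- lapply(seq_along(starts), function(i) {
    from <- starts[i]
    to <- if (i < length(starts)) starts[i + 1L] - 1L else length(lines)
    block <- lines[from:to]
    seg <- as.integer(sub("segsites: *", "", grep("^segsites:", block,
                                                  value = TRUE)))
    if (seg == 0L) return(matrix(0L, 0L, 0L))
    haps <- grep("^[01]+$", block, value = TRUE)
    mat <- do.call(rbind, lapply(strsplit(haps, ""), as.integer))
    rownames(mat) <- paste0("hap", seq_len(nrow(mat)))
    mat
  })
  # monomorphic blocks carry no haplotype rows; recover n from the others
  n <- unique(vapply(loci, nrow, 0L))
  n <- n[n > 0L]
  if (length(n) == 1L)
    loci <- lapply(loci, function(m) {
      if (nrow(m) == 0L) {
        m <- matrix(0L, n, 0L)
        rownames(m) <- paste0("hap", seq_len(n))
      }
      m
    })
  structure(loci, class = "segregating_patterns")
}

#' Write a summary-statistic profile as TSV
#'
#' Per-locus rows followed by a `mean` summary row (the across-locus mean
#' over defined loci).
#'
#' @param profile A `sumstat_profile`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_profile_tsv <- function(profile, file) {
  per <- profile$per_locus
  summary_row <- per[1, ]
  summary_row[1, ] <- NA
  summary_row$locus <- "mean"
  for (s in names(profile$across_loci))
    summary_row[[s]] <- profile$across_loci[[s]]
  out <- rbind(data.frame(lapply(per, as.character)),
               data.frame(lapply(summary_row, as.character)))
  utils::write.table(out, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}
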