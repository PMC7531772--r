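#' Construct an orthogroup count matrix
#'
#' The central observable: per-taxon gene counts for each orthogroup.  Rows
#' are taxa, columns orthogroups; entries are non-negative integers.  A
#' count matrix can carry named tags, each a set of orthogroup IDs (e.g. the
#' focal apoptosis set produced by [map_gene_set()]).
#'
#' @param counts Numeric matrix, taxa x orthogroups, with unique non-empty
#'   row and column names and non-negative integral entries.
#' @param tags Named list of character vectors of orthogroup IDs.
#' @return An object of class `count_matrix` (an integer matrix with a
#'   `tags` attribute).
#' @export
count_matrix <- function(counts, tags = list()) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)) ||
      any(!nzchar(rownames(counts))) || any(!nzchar(colnames(counts)))) {
    stop("count matrix needs non-empty taxon row names and orthogroup column names")
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate taxon IDs")
  if (anyDuplicated(colnames(counts))) stop("duplicate orthogroup IDs")
  if (!is.numeric(counts) || anyNA(counts)) stop("counts must be numeric with no NA")
  if (any(counts < 0)) stop("negative count")
  if (!all(is_wholenumber(counts))) stop("non-integer count")
  storage.mode(counts) <- "integer"
  structure(counts, tags = validate_tags(tags, colnames(counts)),
            class = c("count_matrix", "matrix"))
}

validate_tags <- function(tags, orthogroups) {
  if (length(tags) == 0L) return(list())
  if (is.null(names(tags)) || any(!nzchar(names(tags)))) stop("tags must be named")
  tags <- lapply(tags, as.character)
  for (nm in names(tags)) {
    bad <- setdiff(tags[[nm]], orthogroups)
    if (length(bad)) {
      stop("tag '", nm, "' references unknown orthogroup(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  tags
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("Orthogroup count matrix: %d taxa x %d orthogroups\n",
              nrow(x), ncol(x)))
  tags <- attr(x, "tags")
  for (nm in names(tags)) {
    cat(sprintf("  tag '%s': %d orthogroups\n", nm, length(tags[[nm]])))
  }
  invisible(x)
}

#' Orthogroup tags of a count matrix
#'
#' @param m A [count_matrix()].
#' @return Named list of orthogroup-ID vectors.
#' @export
count_tags <- function(m) attr(m, "tags") %||% list()

#' Read an orthogroup count matrix from TSV
#'
#' Expected layout: header row of orthogroup IDs, first column taxon labels,
#' remaining cells non-negative integer counts.  Empty cells are read as 0
#' with a warning.
#'
#' @param path Path to the TSV file.
#' @param taxa Optional character vector of known taxon labels, used to
#'   detect transposed input (taxon labels appearing in the header): such a
#'   file is rejected with a clear message, never silently transposed.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(path, taxa = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) stop("count matrix needs a taxon column plus >= 1 orthogroup")
  header <- colnames(df)[-1L]
  rows <- df[[1L]]
  if (!is.null(taxa)) {
    in_header <- mean(header %in% taxa)
    in_rows <- mean(rows %in% taxa)
    if (in_header > 0.5 && in_header > in_rows) {
      stop("count matrix appears transposed: taxon labels found in the header. ",
           "Expected taxa as rows and orthogroups as columns.")
    }
  }
  raw <- as.matrix(df[, -1L, drop = FALSE])
  empty <- is.na(raw) | !nzchar(trimws(raw))
  if (any(empty)) {
    warning(sum(empty), " empty cell(s) read as 0", call. = FALSE)
    raw[empty] <- "0"
  }
  num <- suppressWarnings(as.numeric(raw))
  if (anyNA(num)) {
    stop("non-numeric cell(s), e.g. '", raw[which(is.na(num))[1L]], "'")
  }
  counts <- matrix(num, nrow = nrow(raw),
                   dimnames = list(rows, header))
  count_matrix(counts)
}

#' Write a count matrix as TSV
#'
#' Rows and columns are sorted by label, so identical matrices serialise
#' byte-identically regardless of in-memory order.
#'
#' @param m A [count_matrix()] (or plain integer matrix with dimnames).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(m, path) {
  m <- m[order(rownames(m)), order(colnames(m)), drop = FALSE]
  df <- data.frame(taxon = rownames(m), unclass(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read locus-level domain architecture records
#'
#' Format: `taxon<TAB>locus<TAB>domain1;domain2;...` with an optional fourth
#' e-value column; no header; `#` comment lines allowed.  Domain hits are
#' assumed to be pre-filtered (e.g. Pfam scans thresholded upstream).
#'
#' @param path Path to the TSV file.
#' @return A data frame with columns `taxon`, `locus`, `domains`
#'   (semicolon-joined, in locus order) and `evalue` (NA when absent).
#' @export
read_domain_architectures <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(df) < 3L) stop("domain architecture file needs >= 3 columns")
  out <- data.frame(taxon = df[[1L]], locus = df[[2L]], domains = df[[3L]],
                    evalue = if (ncol(df) >= 4L) as.numeric(df[[4L]]) else NA_real_,
                    stringsAsFactors = FALSE)
  if (any(!nzchar(out$taxon)) || any(!nzchar(out$locus))) {
    stop("empty taxon or locus field")
  }
  if (any(!nzchar(out$domains))) stop("record with empty domain list")
  out
}

#' Tabulate per-taxon domain counts
#'
#' Counts occurrences of each vocabulary domain across all of a taxon's
#' loci (a locus carrying two SAM domains contributes 2).  Domains outside
#' the vocabulary are ignored, with a tally reported via `message()`.
#'
#' @param records Data frame as returned by [read_domain_architectures()].
#' @param vocabulary Character vector of domain names to count; default the
#'   four p53-family domains (transactivation, DNA-binding, tetramerisation,
#'   sterile-alpha-motif).
#' @param binarize Collapse counts to presence/absence (0/1), the form used
#'   when mapping domains as Dollo characters.
#' @return Integer matrix, taxa x vocabulary (taxa sorted).  Zero rows if
#'   `records` is empty.
#' @export
tabulate_domain_counts <- function(records,
                                   vocabulary = c("TAD", "p53", "TET", "SAM"),
                                   binarize = FALSE) {
  if (length(vocabulary) == 0L) stop("'vocabulary' must be non-empty")
  taxa <- sort(unique(records$taxon))
  prof <- matrix(0L, nrow = length(taxa), ncol = length(vocabulary),
                 dimnames = list(taxa, vocabulary))
  ignored <- 0L
  if (nrow(records) > 0L) {
    doms <- strsplit(records$domains, ";", fixed = TRUE)
    for (i in seq_along(doms)) {
      d <- trimws(doms[[i]])
      d <- d[nzchar(d)]
      known <- d %in% vocabulary
      ignored <- ignored + sum(!known)
      if (any(known)) {
        tab <- table(factor(d[known], levels = vocabulary))
        prof[records$taxon[i], ] <- prof[records$taxon[i], ] + as.integer(tab)
      }
    }
  }
  if (ignored > 0L) {
    message(ignored, " domain occurrence(s) outside the vocabulary ignored")
  }
  if (binarize) prof <- (prof > 0L) * 1L
  prof
}

#' Read a curated gene to orthogroup map
#'
#' Format: `gene_id<TAB>orthogroup_id` with the literal value `UNMAPPED` for
#' genes that eluded orthology assignment; no header; `#` comments allowed.
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns `gene_id`, `orthogroup`.
#' @export
read_gene_set_map <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE,
                          col.names = c("gene_id", "orthogroup"),
                          colClasses = "character")
  if (anyDuplicated(df$gene_id)) {
    stop("gene(s) mapped more than once: ",
         paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
  }
  df
}

#' Tag the orthogroups hit by a curated gene set
#'
#' Resolves a curated gene list (e.g. KEGG apoptosis loci) to the distinct
#' orthogroups its mapped members fall into, tags those orthogroups on the
#' count matrix, and reports the bookkeeping: how many genes were unmapped,
#' how many mapped, how many distinct orthogroups result, and how many genes
#' share an orthogroup with another (many-to-one homologisation).
#'
#' @param genes Data frame from [read_gene_set_map()].
#' @param m A [count_matrix()].
#' @param tag Name under which the focal orthogroup set is stored.
#' @return List with elements `matrix` (the tagged count matrix) and
#'   `summary` (`total`, `unmapped`, `mapped`, `distinct_orthogroups`,
#'   `genes_sharing_orthogroup`, `unknown_orthogroups`).
#' @export
map_gene_set <- function(genes, m, tag = "focal") {
  if (nrow(genes) == 0L) stop("empty gene set")
  unmapped <- genes$orthogroup == "UNMAPPED"
  og <- genes$orthogroup[!unmapped]
  unknown <- setdiff(og, colnames(m))
  if (length(unknown)) {
    warning(length(unknown), " mapped orthogroup ID(s) absent from the count ",
            "matrix, excluded: ", paste(utils::head(unknown, 5), collapse = ", "),
            call. = FALSE)
  }
  og <- og[og %in% colnames(m)]
  focal <- sort(unique(og))
  tags <- count_tags(m)
  tags[[tag]] <- focal
  summary <- list(
    total = nrow(genes),
    unmapped = sum(unmapped),
    mapped = length(og),
    distinct_orthogroups = length(focal),
    genes_sharing_orthogroup = length(og) - length(focal),
    unknown_orthogroups = length(unknown)
  )
  list(matrix = count_matrix(unclass(m), tags = tags), summary = summary)
}

#' Per-taxon repertoire size over a tagged orthogroup set
#'
#' @param m A [count_matrix()].
#' @param focal Either the name of a tag on `m` or a character vector of
#'   orthogroup IDs.
#' @return Named integer vector of per-taxon summed counts (zeros when the
#'   tagged set is empty).
#' @export
repertoire_size <- function(m, focal = "focal") {
  if (length(focal) == 1L && focal %in% names(count_tags(m))) {
    ids <- count_tags(m)[[focal]]
  } else if (all(focal %in% colnames(m))) {
    ids <- focal
  } else {
    stop("unknown tag or orthogroup ID(s): ",
         paste(setdiff(focal, colnames(m)), collapse = ", "))
  }
  if (length(ids) == 0L) {
    return(stats::setNames(integer(nrow(m)), rownames(m)))
  }
  rowSums(unclass(m)[, ids, drop = FALSE])
}

#' Binarize counts to presence/absence
#'
#' @param m Count matrix.
#' @param threshold Minimum count treated as presence (default 1).
#' @return Integer 0/1 matrix with the same dimnames.
#' @export
binarize_counts <- function(m, threshold = 1L) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L, threshold >= 1)
  out <- (unclass(m) >= threshold) * 1L
  dimnames(out) <- dimnames(m)
  out
}
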