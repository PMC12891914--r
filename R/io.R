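# Readers/writers for the external representations the pipeline touches:
# allele FASTA, long-format genotype TSV, PSS TSV, Newick species trees.
# All validation is strict: malformed input is a hard error naming the
# offending record, column or tip.

#' Construct an allele set
#'
#' An allele set is the unit of QC and diversity: the nucleotide alleles of
#' one locus, with unique IDs and an unrestricted-length ACGT alphabet.
#'
#' @param locus_id Single locus identifier.
#' @param ids Character vector of allele IDs (unique, non-empty).
#' @param seqs Character vector of nucleotide sequences over \{A,C,G,T\},
#'   parallel to `ids`. Ambiguity codes are rejected.
#' @return An object of class `allele_set`: a list with elements `locus_id`,
#'   `allele_id` and `sequence` (parallel character vectors).
#' @examples
#' allele_set("MHCI", c("a", "b"), c("ACG", "TTT"))
#' @export
allele_set <- function(locus_id, ids, seqs) {
  stopifnot(is.character(locus_id), length(locus_id) == 1L)
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  if (length(ids) != length(seqs))
    stop_fmt("allele IDs and sequences differ in length (%d vs %d)",
             length(ids), length(seqs))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop_fmt("duplicate allele ID(s) in locus '%s': %s", locus_id,
             paste(unique(dup), collapse = ", "))
  if (any(!nzchar(seqs)))
    stop_fmt("empty sequence for allele '%s'", ids[!nzchar(seqs)][1L])
  bad <- regexpr("[^ACGT]", seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop_fmt("non-ACGT character '%s' in allele '%s' at position %d",
             substr(seqs[i], bad[i], bad[i]), ids[i], bad[i])
  }
  structure(list(locus_id = locus_id, allele_id = ids, sequence = seqs),
            class = "allele_set")
}

#' @export
print.allele_set <- function(x, ...) {
  cat(sprintf("Allele set: locus '%s', %d allele(s), lengths %s\n",
              x$locus_id, length(x$allele_id),
              paste(range(nchar(x$sequence)), collapse = "-")))
  invisible(x)
}

#' @export
length.allele_set <- function(x) length(x$allele_id)

# Subset an allele set by logical/index/ID, preserving order.
subset_alleles <- function(x, keep) {
  if (is.character(keep)) keep <- match(keep, x$allele_id)
  allele_set(x$locus_id, x$allele_id[keep], x$sequence[keep])
}

#' Read per-locus alleles from FASTA
#'
#' One record per FASTA entry, order preserved; the description after the
#' first whitespace is ignored. Duplicate IDs and non-ACGT characters are
#' hard errors (the error names the record and 1-based position).
#'
#' @param path Path to a FASTA file.
#' @param locus_id Locus identifier attached to the resulting set.
#' @return An [allele_set()].
#' @export
read_allele_fasta <- function(path, locus_id) {
  if (!file.exists(path)) stop_fmt("FASTA file not found: %s", path)
  dss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(dss))
  allele_set(locus_id, ids, as.character(dss))
}

#' Write an allele set to FASTA
#'
#' @param alleles An [allele_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_allele_fasta <- function(alleles, path) {
  x <- Biostrings::BStringSet(alleles$sequence)
  names(x) <- alleles$allele_id
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Read a long-format genotype table
#'
#' Expected: tab-delimited with header columns `individual_id`, `species`,
#' `locus`, `run_id`, `allele_id`; one allele call per row. Exact duplicate
#' rows are collapsed with a warning stating how many were dropped.
#'
#' @param path Path to a TSV file.
#' @return A `data.frame` with the five columns above (class
#'   `genotype_table`/`data.frame`).
#' @export
read_genotype_table <- function(path) {
  if (!file.exists(path)) stop_fmt("genotype table not found: %s", path)
  df <- utils::read.delim(path, colClasses = "character",
                          check.names = FALSE, stringsAsFactors = FALSE)
  genotype_table(df)
}

#' Construct/validate a genotype table
#'
#' @param df Data frame with columns `individual_id`, `species`, `locus`,
#'   `run_id`, `allele_id`.
#' @return The validated, duplicate-collapsed data frame.
#' @export
genotype_table <- function(df) {
  required <- c("individual_id", "species", "locus", "run_id", "allele_id")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop_fmt("genotype table missing column(s): %s",
             paste(missing, collapse = ", "))
  df <- df[, required, drop = FALSE]
  if (nrow(df) == 0L) stop_fmt("genotype table is empty")
  dups <- duplicated(df)
  if (any(dups)) {
    warn_fmt("%d duplicate genotype row(s) collapsed", sum(dups))
    df <- df[!dups, , drop = FALSE]
  }
  rownames(df) <- NULL
  class(df) <- c("genotype_table", "data.frame")
  df
}

#' Read a positively-selected-sites list
#'
#' Tab-delimited with header columns `locus` and `codon`; codon indices are
#' 1-based within the trimmed open reading frame. Duplicates are rejected.
#'
#' @param path Path to a TSV file.
#' @param locus_id Optional locus to filter on; if given, returns the sorted
#'   integer codon indices for that locus, else the full data frame.
#' @return Integer vector of codon indices (with `locus_id`) or a data frame.
#' @export
read_pss_list <- function(path, locus_id = NULL) {
  if (!file.exists(path)) stop_fmt("PSS list not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("locus", "codon"), names(df))
  if (length(missing))
    stop_fmt("PSS list missing column(s): %s", paste(missing, collapse = ", "))
  df$codon <- as.integer(df$codon)
  if (is.null(locus_id)) return(df)
  idx <- sort(df$codon[df$locus == locus_id])
  if (anyDuplicated(idx))
    stop_fmt("duplicate PSS codon index for locus '%s'", locus_id)
  if (length(idx) && idx[1L] < 1L)
    stop_fmt("PSS codon indices must be >= 1 (locus '%s')", locus_id)
  idx
}

#' Read a species tree from Newick
#'
#' Branch lengths are required on every edge used for distances; internal
#' node labels are ignored.
#'
#' @param path Path to a Newick file (or a Newick string via `text`).
#' @param text Optional Newick string; overrides `path`.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_species_tree <- function(path = NULL, text = NULL) {
  tree <- if (!is.null(text)) ape::read.tree(text = text) else {
    if (!file.exists(path)) stop_fmt("tree file not found: %s", path)
    ape::read.tree(path)
  }
  if (is.null(tree)) stop_fmt("could not parse Newick tree")
  if (is.null(tree$edge.length))
    stop_fmt("species tree has no branch lengths")
  if (any(tree$edge.length < 0))
    stop_fmt("species tree has negative branch lengths")
  tree
}

#' Patristic distance between two tips
#'
#' Sum of branch lengths on the unique path between two tips; symmetric and
#' zero iff the tips are identical.
#'
#' @param tree A `phylo` object with branch lengths.
#' @param tip_a,tip_b Tip labels.
#' @return Non-negative numeric distance in substitutions/site.
#' @examples
#' tr <- read_species_tree(text = "((A:1,B:2):0.5,C:3);")
#' patristic_distance(tr, "A", "C")  # 4.5
#' @export
patristic_distance <- function(tree, tip_a, tip_b) {
  for (tip in c(tip_a, tip_b))
    if (!tip %in% tree$tip.label)
      stop_fmt("tip '%s' not found in species tree", tip)
  if (tip_a == tip_b) return(0)
  d <- ape::cophenetic.phylo(tree)
  unname(d[tip_a, tip_b])
}

# All pairwise tip distances as a matrix (single cophenetic call).
patristic_matrix <- function(tree) ape::cophenetic.phylo(tree)

#' Fetch nucleotide records from GenBank as FASTA
#'
#' Thin wrapper around NCBI E-utilities `efetch` used for accession-level
#' checks against deposited alleles. Requires network access; fails with a
#' clear error otherwise.
#'
#' @param accessions Character vector of accession IDs (e.g. "PQ227852.1").
#' @param dest Output FASTA path.
#' @param timeout Seconds before each request is abandoned.
#' @return `dest`, invisibly.
#' @export
fetch_genbank_fasta <- function(accessions, dest,
                                timeout = 30) {
  base <- "https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi"
  con <- file(dest, open = "wb")
  on.exit(close(con), add = TRUE)
  # chunk to stay under URL length limits
  chunks <- split(accessions, ceiling(seq_along(accessions) / 150))
  old <- getOption("timeout"); options(timeout = timeout)
  on.exit(options(timeout = old), add = TRUE)
  for (ch in chunks) {
    url <- sprintf("%s?db=nuccore&rettype=fasta&retmode=text&id=%s",
                   base, paste(ch, collapse = ","))
    ok <- tryCatch({
      txt <- suppressWarnings(readLines(url, warn = FALSE))
      writeLines(txt, con)
      TRUE
    }, error = function(e) FALSE)
    if (!ok)
      stop_fmt("could not fetch %d record(s) from GenBank (network unavailable?)",
               length(ch))
  }
  invisible(dest)
}

#' Expand a GenBank accession range
#'
#' `accession_range("PQ227852.1", "PQ227878.1")` enumerates the inclusive
#' numeric run sharing one alphabetic prefix and version.
#'
#' @param from,to First and last accession of the run.
#' @return Character vector of accessions.
#' @export
accession_range <- function(from, to) {
  parse1 <- function(x) {
    m <- regmatches(x, regexec("^([A-Za-z]+)([0-9]+)(\\.[0-9]+)?$", x))[[1]]
    if (length(m) == 0L) stop_fmt("cannot parse accession '%s'", x)
    list(prefix = m[2], num = m[3], ver = m[4])
  }
  a <- parse1(from); b <- parse1(to)
  if (a$prefix != b$prefix || a$ver != b$ver)
    stop_fmt("accession range endpoints do not match: %s .. %s", from, to)
  width <- nchar(a$num)
  nums <- seq(as.integer(a$num), as.integer(b$num))
  sprintf("%s%0*d%s", a$prefix, width, nums, a$ver)
}
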