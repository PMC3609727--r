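# Trees, alignments, column masking and clade resolution.
#
# Trees are plain ape "phylo" objects with branch lengths in expected
# substitutions per site; alignments are a light S3 container over upper-case
# character strings so that masking and pairwise comparison stay simple.

.DNA_ALPHABET <- c("A", "C", "G", "T",                      # unambiguous
                   "R", "Y", "S", "W", "K", "M",            # 2-fold IUPAC
                   "B", "D", "H", "V", "N",                 # 3/4-fold IUPAC
                   "-")                                     # alignment gap

#' Read a phylogram from a Newick file
#'
#' Parses a rooted Newick tree with branch lengths in expected substitutions
#' per site. Support values on internal nodes are tolerated and ignored.
#' Trees whose root has more than two children (typical of unrooted input)
#' are accepted as rooted at the basal node, with a warning, since downstream
#' dating requires a root. Single-tip trees are accepted and flagged
#' degenerate.
#'
#' @param path Path to a Newick file (single tree).
#' @return An [ape::read.tree()] `phylo` object; branch lengths preserved at
#'   full precision.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("Newick file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  validate_phylogram(parse_newick_text(txt))
}

# Shared by read_newick and tests; gives a character offset on bracket
# imbalance, which ape's parser does not report.
parse_newick_text <- function(txt) {
  depth <- 0L
  chars <- strsplit(txt, "", fixed = TRUE)[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop(sprintf("malformed Newick: unmatched ')' at character %d", i))
    }
  }
  if (depth != 0L)
    stop(sprintf("malformed Newick: %d unclosed '(' at end of input", depth))
  tr <- tryCatch(ape::read.tree(text = txt),
                 error = function(e) stop("malformed Newick: ",
                                          conditionMessage(e), call. = FALSE))
  if (is.null(tr)) stop("malformed Newick: parser returned no tree")
  tr
}

# Invariant checks shared by all tree entry points.
validate_phylogram <- function(tr) {
  stopifnot(inherits(tr, "phylo"))
  if (any(tr$tip.label == "" | is.na(tr$tip.label)))
    stop("tip labels must be non-empty")
  dup <- tr$tip.label[duplicated(tr$tip.label)]
  if (length(dup)) stop("duplicate tip labels: ", paste(dup, collapse = ", "))
  if (is.null(tr$edge.length))
    stop("branch lengths missing on all edges")
  if (anyNA(tr$edge.length)) {
    bad <- tr$edge[is.na(tr$edge.length), 2]
    lab <- ifelse(bad <= length(tr$tip.label),
                  tr$tip.label[pmin(bad, length(tr$tip.label))],
                  paste0("node_", bad))
    stop("missing branch length on edge(s) leading to: ",
         paste(lab, collapse = ", "))
  }
  if (any(tr$edge.length < 0))
    stop("negative branch lengths are not allowed")
  if (length(tr$tip.label) == 1L)
    warning("degenerate single-tip tree")
  root <- tree_root(tr)
  if (sum(tr$edge[, 1] == root) > 2L)
    warning("root has >2 children (basal polytomy / unrooted input); ",
            "treating the basal node as the root")
  tr
}

tree_root <- function(tr) {
  if (length(tr$tip.label) == 1L) return(2L)
  unique(tr$edge[!(tr$edge[, 1] %in% tr$edge[, 2]), 1])
}

#' Write a phylogram to a Newick file
#'
#' Round-trips with [read_newick()] up to floating-point formatting
#' (10 significant digits).
#'
#' @param tree A `phylo` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 10)
  invisible(path)
}

#' DNA alignment container
#'
#' Stores aligned sequences as upper-case character strings over the DNA
#' alphabet (A/C/G/T), IUPAC ambiguity codes and the gap symbol `-`.
#' IUPAC codes are retained; their treatment (pairwise deletion) is decided
#' by the diversity computations.
#'
#' @param seqs Character vector of aligned sequences.
#' @param labels Sequence labels; defaults to `names(seqs)`.
#' @return An object of class `dna_alignment` with fields `labels`, `seqs`
#'   and `ncol`.
#' @export
dna_alignment <- function(seqs, labels = names(seqs)) {
  if (is.null(labels)) stop("sequence labels are required")
  labels <- as.character(labels)
  seqs <- toupper(as.character(seqs))
  if (length(seqs) < 1L) stop("alignment needs at least one record")
  if (any(labels == "" | is.na(labels))) stop("labels must be non-empty")
  dup <- labels[duplicated(labels)]
  if (length(dup)) stop("duplicate labels: ", paste(dup, collapse = ", "))
  len <- nchar(seqs)
  if (length(unique(len)) != 1L) {
    off <- labels[len != len[1]]
    stop("ragged alignment: records differ in length from the first (",
         len[1], " columns): ", paste(off, collapse = ", "))
  }
  for (i in seq_along(seqs)) {
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    bad <- which(!(ch %in% .DNA_ALPHABET))
    if (length(bad))
      stop(sprintf("illegal symbol '%s' in record '%s' at position %d (DNA alphabet only)",
                   ch[bad[1]], labels[i], bad[1]))
  }
  structure(list(labels = labels, seqs = unname(seqs), ncol = len[1]),
            class = "dna_alignment")
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat("dna_alignment:", length(x$labels), "sequences x", x$ncol, "columns\n")
  invisible(x)
}

# Character matrix view (rows = sequences), used by masking and diversity.
alignment_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$seqs, "", fixed = TRUE))
  rownames(m) <- aln$labels
  m
}

#' Read a FASTA alignment
#'
#' Accepts wrapped or single-line FASTA. Sequences are upper-cased and
#' validated: equal lengths, unique labels, DNA alphabet plus IUPAC codes
#' and gaps ('U' is rejected). The label is the full header line after `>`,
#' trimmed.
#'
#' @param path Path to a FASTA file with at least one record.
#' @return A [dna_alignment()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no FASTA records in ", path)
  if (length(lines) && !grepl("^>", lines[1][lines[1] != ""][1]) &&
      hdr[1] != which(lines != "")[1])
    stop("FASTA must start with a '>' header line")
  labels <- trimws(sub("^>", "", lines[hdr]))
  bounds <- c(hdr, length(lines) + 1L)
  seqs <- vapply(seq_along(hdr), function(i) {
    body <- lines[seq(bounds[i] + 1L, bounds[i + 1L] - 1L)]
    paste(gsub("[ \t]", "", body), collapse = "")
  }, character(1))
  dna_alignment(seqs, labels)
}

#' Write an alignment to FASTA
#'
#' @param aln A [dna_alignment()].
#' @param path Output path.
#' @param width Line-wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(aln, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(aln$labels)) {
    writeLines(paste0(">", aln$labels[i]), con)
    s <- aln$seqs[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Parse a masked-region specification
#'
#' Converts a comma-separated `"start-end"` string (1-based, inclusive, the
#' convention used to exclude ambiguously aligned regions such as
#' `"53-55,194-198,429-444"`) into a two-column integer matrix.
#'
#' @param spec Character scalar, e.g. `"53-55,194-198"`; empty string or
#'   `NULL` means no masking.
#' @return Integer matrix with columns `start`, `end` (possibly 0 rows).
#' @export
parse_mask_ranges <- function(spec) {
  if (is.null(spec) || !nzchar(trimws(spec)))
    return(matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end"))))
  parts <- strsplit(trimws(spec), ",", fixed = TRUE)[[1]]
  m <- t(vapply(parts, function(p) {
    se <- suppressWarnings(as.integer(strsplit(trimws(p), "-", fixed = TRUE)[[1]]))
    if (length(se) != 2L || anyNA(se))
      stop("bad mask interval: '", p, "' (expected 'start-end')")
    se
  }, integer(2)))
  dimnames(m) <- list(NULL, c("start", "end"))
  m
}

#' Remove alignment columns inside masked intervals
#'
#' Drops the union of the given 1-based inclusive column intervals (which may
#' overlap) and returns the alignment of the remaining columns in their
#' original relative order. With no intervals this is the identity.
#'
#' @param aln A [dna_alignment()].
#' @param ranges A two-column matrix of `start`,`end` (1-based inclusive), a
#'   list of length-2 vectors, or a character spec for
#'   [parse_mask_ranges()].
#' @return A [dna_alignment()] with the masked columns removed.
#' @export
mask_columns <- function(aln, ranges) {
  stopifnot(inherits(aln, "dna_alignment"))
  if (is.character(ranges)) ranges <- parse_mask_ranges(ranges)
  if (is.list(ranges)) ranges <- do.call(rbind, ranges)
  if (is.null(ranges) || nrow(ranges) == 0L) return(aln)
  ranges <- matrix(as.integer(ranges), ncol = 2)
  if (any(ranges[, 1] > ranges[, 2]))
    stop("mask interval with start > end")
  if (any(ranges < 1L) || any(ranges > aln$ncol))
    stop("mask interval out of bounds [1, ", aln$ncol, "]")
  drop <- rep(FALSE, aln$ncol)
  for (i in seq_len(nrow(ranges)))
    drop[seq(ranges[i, 1], ranges[i, 2])] <- TRUE
  m <- alignment_matrix(aln)[, !drop, drop = FALSE]
  dna_alignment(apply(m, 1L, paste, collapse = ""), aln$labels)
}

#' Descendant tip-set key of every node
#'
#' Returns, for each node (ape numbering), the sorted semicolon-joined
#' labels of its descendant tips (a tip's key is its own label). These keys
#' identify nodes independently of the numbering a Newick round trip
#' assigns, and are used to key fixture ground-truth tables.
#'
#' @param tree A `phylo` object.
#' @return Character vector of length `ntip + nnode`.
#' @export
node_tip_keys <- function(tree) {
  s <- .pl_structure(tree)
  sets <- vector("list", s$N)
  sets[seq_len(s$ntip)] <- as.list(tree$tip.label)
  for (e in s$po)
    sets[[s$E[e, 1]]] <- c(sets[[s$E[e, 1]]], sets[[s$E[e, 2]]])
  vapply(sets, function(x) paste(sort(x), collapse = ";"), character(1))
}

#' Define a clade by its tip set
#'
#' @param name Clade name.
#' @param tips Character vector of tip labels (nonempty).
#' @param n_min Species count included in the analysis (>= 1); by convention
#'   the number of species actually sampled.
#' @param n_max_known Optional literature species count (>= n_min), `NA` if
#'   unknown (it is then extrapolated from sampling fractions downstream).
#' @return An object of class `clade_definition`.
#' @export
clade_definition <- function(name, tips, n_min, n_max_known = NA_integer_) {
  tips <- as.character(tips)
  if (!length(tips)) stop("clade '", name, "': tips must be nonempty")
  if (anyDuplicated(tips)) stop("clade '", name, "': duplicated tips")
  n_min <- as.integer(n_min)
  if (is.na(n_min) || n_min < 1L) stop("clade '", name, "': n_min must be >= 1")
  if (!is.na(n_max_known)) {
    n_max_known <- as.integer(n_max_known)
    if (n_max_known < n_min)
      stop("clade '", name, "': n_max_known < n_min")
  }
  structure(list(name = as.character(name), tips = tips, n_min = n_min,
                 n_max_known = n_max_known),
            class = "clade_definition")
}

#' Read clade definitions from a TSV file
#'
#' Expected columns: `name`, `n_min`, `n_max_known` (optional; blank or NA
#' when unknown), `tips` (semicolon-separated tip labels).
#'
#' @param path Path to the TSV file.
#' @return A named list of [clade_definition()] objects.
#' @export
read_clades <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "n_min", "tips")
  if (!all(need %in% names(d)))
    stop("clades file must have columns: ", paste(need, collapse = ", "))
  if (!"n_max_known" %in% names(d)) d$n_max_known <- NA_integer_
  out <- lapply(seq_len(nrow(d)), function(i) {
    nmk <- d$n_max_known[i]
    if (is.character(nmk) && !nzchar(trimws(nmk))) nmk <- NA
    clade_definition(d$name[i],
                     trimws(strsplit(d$tips[i], ";", fixed = TRUE)[[1]]),
                     d$n_min[i],
                     suppressWarnings(as.integer(nmk)))
  })
  names(out) <- d$name
  out
}

#' Extract the subtree spanned by a clade
#'
#' Returns the subtree rooted at the most recent common ancestor (MRCA) of
#' the clade's tips, together with a monophyly flag: `TRUE` iff the MRCA
#' subtree contains exactly the clade's tips.
#'
#' @param tree A `phylo` object.
#' @param clade A [clade_definition()] or a character vector of tip labels.
#' @return A list with elements `tree` (the MRCA subtree), `monophyletic`
#'   (logical) and `mrca` (node number in `tree`).
#' @export
extract_clade <- function(tree, clade) {
  tips <- if (inherits(clade, "clade_definition")) clade$tips else as.character(clade)
  unknown <- setdiff(tips, tree$tip.label)
  if (length(unknown))
    stop("unknown tip label(s): ", paste(unknown, collapse = ", "))
  if (length(tips) == 1L) {
    warning("single-tip clade; returning the tip as a degenerate subtree")
    sub <- ape::keep.tip(tree, tips)
    return(list(tree = sub, monophyletic = TRUE,
                mrca = match(tips, tree$tip.label)))
  }
  mrca <- ape::getMRCA(tree, tips)
  sub <- if (mrca == tree_root(tree)) tree else ape::extract.clade(tree, mrca)
  list(tree = sub,
       monophyletic = setequal(sub$tip.label, tips),
       mrca = mrca)
}
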