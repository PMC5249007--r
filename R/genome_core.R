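## Data model for signed circular genomes as adjacency sets.
##
## A genome over n signed genes is a perfect matching of the 2n gene ends
## into n adjacencies.  Gene ends are encoded as integers in 1..2n:
## tail(g) = 2g - 1, head(g) = 2g.  An adjacency is an unordered pair of
## distinct ends; the two ends of one gene may be paired (a minimal
## circular chromosome).

#' Gene-end encoding
#'
#' Gene ends are integers in \code{1..2n}: the tail of gene \code{g} is
#' \code{2g - 1} and its head is \code{2g}.  These helpers convert between
#' genes and ends.
#'
#' @param g integer vector of gene identifiers (1-based).
#' @param e integer vector of gene-end codes.
#' @return \code{gene_tail}/\code{gene_head} return end codes;
#'   \code{end_gene} returns gene identifiers; \code{end_is_head} a logical
#'   vector; \code{end_label} a character vector such as \code{"3h"}.
#' @examples
#' gene_tail(1:3)
#' end_label(gene_head(2))
#' @export
gene_tail <- function(g) 2L * as.integer(g) - 1L

#' @rdname gene_tail
#' @export
gene_head <- function(g) 2L * as.integer(g)

#' @rdname gene_tail
#' @export
end_gene <- function(e) (as.integer(e) + 1L) %/% 2L

#' @rdname gene_tail
#' @export
end_is_head <- function(e) as.integer(e) %% 2L == 0L

#' @rdname gene_tail
#' @export
end_label <- function(e) {
  paste0(end_gene(e), ifelse(end_is_head(e), "h", "t"))
}

## canonical form: each row (min, max), rows ordered lexicographically
.canonical_adj <- function(adj) {
  adj <- cbind(pmin(adj[, 1L], adj[, 2L]), pmax(adj[, 1L], adj[, 2L]))
  storage.mode(adj) <- "integer"
  adj[order(adj[, 1L], adj[, 2L]), , drop = FALSE]
}

## order-insensitive hash of adjacencies; double to avoid integer overflow
.adj_keys <- function(adj, n) {
  (pmin(adj[, 1L], adj[, 2L]) - 1) * (2 * n) + pmax(adj[, 1L], adj[, 2L])
}

.as_adj_matrix <- function(candidate) {
  if (is.matrix(candidate)) {
    if (ncol(candidate) != 2L)
      stop("adjacency matrix must have two columns (the two gene ends)")
    adj <- candidate
  } else if (is.list(candidate)) {
    if (!all(lengths(candidate) == 2L))
      stop("each adjacency must be a pair of gene ends")
    adj <- do.call(rbind, lapply(candidate, as.integer))
  } else {
    stop("adjacencies must be a two-column matrix or a list of pairs")
  }
  storage.mode(adj) <- "integer"
  adj
}

#' Validate a candidate adjacency set as a genome
#'
#' Checks that a set of adjacencies forms a valid signed circular genome on
#' \code{n} genes: every adjacency pairs two distinct gene ends in
#' \code{1..2n}, no gene end occurs in more than one adjacency, and the set
#' has cardinality exactly \code{n} (a perfect matching of the \code{2n}
#' ends).  Pairing the two ends of the same gene is allowed and yields a
#' single-gene circular chromosome.
#'
#' @param candidate a two-column integer matrix of gene-end codes (one row
#'   per adjacency) or a list of length-2 vectors; see \code{\link{gene_tail}}
#'   for the end encoding.
#' @param n the gene count.
#' @return an object of class \code{"genome"}: a list with elements
#'   \code{n} and \code{adj}, the canonicalized adjacency matrix.
#' @examples
#' validate_genome(rbind(c(gene_tail(1), gene_head(1))), n = 1)
#' @export
validate_genome <- function(candidate, n) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 1L)
    stop("n must be a positive integer")
  adj <- .as_adj_matrix(candidate)
  if (nrow(adj) == 0L)
    stop("candidate adjacency set is empty")
  if (any(is.na(adj)) || any(adj < 1L) || any(adj > 2L * n))
    stop("gene-end codes must lie in 1..2n (gene identifiers in 1..", n, ")")
  if (any(adj[, 1L] == adj[, 2L]))
    stop("an adjacency must pair two distinct gene ends")
  ends <- as.vector(adj)
  dup <- ends[duplicated(ends)]
  if (length(dup) > 0L)
    stop("incompatible adjacency set: gene end ", end_label(dup[1L]),
         " is part of more than one adjacency")
  if (nrow(adj) != n)
    stop("structural error: expected ", n, " adjacencies, got ", nrow(adj))
  structure(list(n = n, adj = .canonical_adj(adj)), class = "genome")
}

.check_genome <- function(g) {
  if (!inherits(g, "genome"))
    stop("expected a 'genome' object (see validate_genome)")
  g
}

.check_same_n <- function(...) {
  ns <- vapply(list(...), function(g) .check_genome(g)$n, integer(1L))
  if (length(unique(ns)) != 1L)
    stop("structural error: genomes have different gene counts (",
         paste(ns, collapse = ", "), ")")
  ns[1L]
}

#' @export
print.genome <- function(x, ...) {
  chrs <- chromosomes(x)
  cat("Signed circular genome: ", x$n, " genes, ",
      length(chrs), " chromosome", if (length(chrs) != 1L) "s", "\n",
      sep = "")
  show <- utils::head(chrs, 5L)
  for (ch in show) cat("  (", paste(ch, collapse = " "), ")\n", sep = "")
  if (length(chrs) > 5L) cat("  ... and ", length(chrs) - 5L, " more\n", sep = "")
  invisible(x)
}

## partner[e] = end matched with e, for all 2n ends
.partner_vector <- function(g) {
  p <- integer(2L * g$n)
  p[g$adj[, 1L]] <- g$adj[, 2L]
  p[g$adj[, 2L]] <- g$adj[, 1L]
  p
}

#' Decompose a genome into circular chromosomes
#'
#' Traverses the cycles of the graph whose edges are the gene edges (pairing
#' the two ends of each gene) and the adjacency edges.  Every such cycle is
#' a circular chromosome.  Each chromosome is canonicalized: it starts at
#' its smallest gene identifier, oriented so that this gene carries a
#' positive sign.
#'
#' @param g a \code{"genome"} object.
#' @return a list of integer vectors of signed genes, one per circular
#'   chromosome, ordered by their smallest gene.
#' @examples
#' g <- adjacencies_from_gene_order(list(c(1, -2), c(3)))
#' chromosomes(g)
#' @export
chromosomes <- function(g) {
  .check_genome(g)
  partner <- .partner_vector(g)
  seen <- logical(g$n)
  out <- list()
  for (start in seq_len(g$n)) {
    if (seen[start]) next
    chr <- integer(0)
    e <- gene_tail(start)          # enter smallest gene at its tail: sign +
    repeat {
      gn <- end_gene(e)
      seen[gn] <- TRUE
      if (end_is_head(e)) {        # entered at head: traversed against polarity
        chr <- c(chr, -gn)
        exit <- gene_tail(gn)
      } else {
        chr <- c(chr, gn)
        exit <- gene_head(gn)
      }
      e <- partner[exit]
      if (e == gene_tail(start)) break
    }
    out[[length(out) + 1L]] <- chr
  }
  out
}

#' Build a genome from circular gene orders
#'
#' Converts one or more circular orderings of signed genes into the genome's
#' adjacency set.  Consecutive signed genes \code{(+i, +j)} yield the
#' adjacency (head of i, tail of j); a negative sign swaps head and tail;
#' the last gene of each chromosome wraps around to the first.
#'
#' @param orders a list of integer vectors of signed genes (or a single
#'   vector for a unichromosomal genome).  Over all chromosomes each gene
#'   \code{1..n} must appear exactly once.
#' @return a \code{"genome"} object; inverse of \code{\link{chromosomes}}
#'   up to canonical rotation and reflection.
#' @examples
#' adjacencies_from_gene_order(list(c(1, 2, 3, 4)))
#' @export
adjacencies_from_gene_order <- function(orders) {
  if (!is.list(orders)) orders <- list(orders)
  genes <- abs(unlist(orders))
  if (length(genes) == 0L) stop("no genes given")
  if (any(genes < 1L) || any(genes != floor(genes)))
    stop("genes must be nonzero integers")
  n <- length(genes)
  if (anyDuplicated(genes))
    stop("structural error: gene ", genes[duplicated(genes)][1L],
         " appears more than once")
  if (!setequal(genes, seq_len(n)))
    stop("structural error: genes must be exactly 1..", n,
         " (missing: ", paste(setdiff(seq_len(n), genes), collapse = " "), ")")
  rows <- lapply(orders, function(chr) {
    chr <- as.integer(chr)
    exit <- ifelse(chr > 0L, gene_head(abs(chr)), gene_tail(abs(chr)))
    entry <- ifelse(chr > 0L, gene_tail(abs(chr)), gene_head(abs(chr)))
    cbind(exit, entry[c(seq_along(chr)[-1L], 1L)])
  })
  validate_genome(do.call(rbind, rows), n)
}

#' Read and write gene-order files
#'
#' The text dialect is GRIMM/UniMoG-style: a header line \code{">name"} per
#' genome, followed by one line per chromosome of whitespace-separated
#' signed integers terminated by \code{")"} (circular).  The model is
#' circular-only: linear terminators (\code{"$"}, \code{"|"}) are rejected.
#'
#' @param file path to a gene-order file, or \code{NULL} if \code{text} is
#'   given.
#' @param text a character scalar (or vector of lines) holding the file
#'   content directly.
#' @return \code{read_gene_orders} returns a named list of \code{"genome"}
#'   objects; \code{write_gene_orders} returns the text invisibly (and
#'   writes it to \code{file} if non-\code{NULL}).  Writing then reading is
#'   the identity on canonicalized genomes.
#' @examples
#' gs <- read_gene_orders(text = ">g1\n1 2 3 )\n>g2\n1 -2 ) 3 )\n")
#' cat(write_gene_orders(gs))
#' @export
read_gene_orders <- function(file = NULL, text = NULL) {
  if (is.null(text)) {
    if (is.null(file)) stop("give either 'file' or 'text'")
    lines <- readLines(file, warn = FALSE)
  } else {
    lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  }
  genomes <- list()
  cur_name <- NULL
  cur_orders <- list()
  flush <- function() {
    if (is.null(cur_name)) return()
    if (length(cur_orders) == 0L)
      stop("parse error: genome '", cur_name, "' has no chromosomes")
    genomes[[cur_name]] <<- adjacencies_from_gene_order(cur_orders)
  }
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (line == "" || startsWith(line, "#")) next
    if (startsWith(line, ">")) {
      flush()
      cur_name <- trimws(substring(line, 2L))
      if (cur_name == "")
        stop("parse error at line ", i, ": empty genome name")
      cur_orders <- list()
      next
    }
    if (is.null(cur_name))
      stop("parse error at line ", i, ": gene data before any '>' header")
    toks <- strsplit(line, "[[:space:]]+")[[1L]]
    chr <- integer(0)
    for (tok in toks) {
      if (tok == ")") {
        if (length(chr) == 0L)
          stop("parse error at line ", i, ": empty chromosome")
        cur_orders[[length(cur_orders) + 1L]] <- chr
        chr <- integer(0)
      } else if (tok %in% c("$", "|")) {
        stop("parse error at line ", i, ": linear chromosome terminator '",
             tok, "' not supported; the model is circular-only (use ')')")
      } else if (grepl("^-?[0-9]+$", tok)) {
        chr <- c(chr, as.integer(tok))
      } else {
        stop("parse error at line ", i, ": unknown token '", tok, "'")
      }
    }
    if (length(chr) > 0L)
      stop("parse error at line ", i,
           ": chromosome not terminated by ')' (circular)")
  }
  flush()
  if (length(genomes) == 0L) stop("parse error: no genomes found")
  genomes
}

#' @param genomes a named list of \code{"genome"} objects (unnamed entries
#'   are written as \code{genome1}, \code{genome2}, ...).
#' @rdname read_gene_orders
#' @export
write_gene_orders <- function(genomes, file = NULL) {
  if (inherits(genomes, "genome")) genomes <- list(genomes)
  nms <- names(genomes)
  if (is.null(nms)) nms <- rep("", length(genomes))
  blank <- nms == ""
  nms[blank] <- paste0("genome", which(blank))
  out <- character(0)
  for (i in seq_along(genomes)) {
    g <- .check_genome(genomes[[i]])
    out <- c(out, paste0(">", nms[i]),
             vapply(chromosomes(g),
                    function(ch) paste(c(ch, ")"), collapse = " "),
                    character(1L)))
  }
  text <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(file)) writeLines(out, file)
  invisible(text)
}
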