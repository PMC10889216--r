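#' Circular signed gene order
#'
#' A genome reduced to the circular ordered list of its genes with
#' orientations ("+" = major strand).  Built directly or from an annotated
#' genome.
#'
#' @param id genome id.
#' @param genes character vector of gene names in circular order.
#' @param strand character vector of "+"/"-" orientations (same length).
#' @return object of class \code{gene_order}.
#' @export
gene_order <- function(id, genes, strand) {
  stopifnot(length(genes) == length(strand),
            all(strand %in% c("+", "-")))
  if (anyDuplicated(genes))
    stop("duplicate gene token(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  if (length(genes) > 37L) stop("more than 37 genes in order")
  structure(list(id = id, genes = as.character(genes),
                 strand = as.character(strand)),
            class = "gene_order")
}

#' @rdname gene_order
#' @param genome a \code{mito_genome}.
#' @export
as_gene_order <- function(genome) {
  gene_order(genome$id, genome$features$gene, genome$features$strand)
}

#' Signed tokens of a gene order
#' @param order a \code{gene_order}.
#' @return character vector like \code{"+cox1"}, \code{"-trnQ"}.
#' @export
order_tokens <- function(order) paste0(order$strand, order$genes)

#' @export
print.gene_order <- function(x, ...) {
  cat(x$id, ":", paste(order_tokens(x), collapse = " "), "\n")
  invisible(x)
}

#' Read/write gene-order files
#'
#' One line per genome: the id followed by whitespace-separated signed gene
#' tokens (\code{+gene} major strand, \code{-gene} minor strand).  Lines
#' starting with \code{#} are comments.
#'
#' @param path file path.
#' @return list of \code{gene_order} objects (named by id).
#' @export
read_gene_orders <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("no gene orders in ", path)
  out <- lapply(lines, function(l) {
    parts <- strsplit(l, "\\s+")[[1]]
    tokens <- parts[-1]
    sign <- substr(tokens, 1, 1)
    if (!all(sign %in% c("+", "-")))
      stop("tokens must be signed (+gene/-gene) on line: ", l)
    gene_order(parts[1], substring(tokens, 2), sign)
  })
  stats::setNames(out, vapply(out, `[[`, "", "id"))
}

#' @rdname read_gene_orders
#' @param orders list of \code{gene_order}.
#' @export
write_gene_orders <- function(orders, path) {
  lines <- vapply(orders, function(o)
    paste(o$id, paste(order_tokens(o), collapse = " ")), "")
  writeLines(lines, path)
  invisible(path)
}

#' Canonical linearization of a circular gene order
#'
#' Rotates the circle so \code{cox1} comes first; when \code{cox1} lies on the
#' minor strand the whole order is first reflected (read in the opposite
#' direction with all orientations flipped) so that \code{cox1} reads "+".
#' Pure and idempotent: the same circular arrangement always normalizes to the
#' same linear token sequence regardless of the start gene or reading
#' direction of the input.
#'
#' @param order a \code{gene_order} containing \code{cox1}.
#' @return normalized \code{gene_order}.
#' @export
normalize_gene_order <- function(order) {
  i <- match("cox1", order$genes)
  if (is.na(i)) stop("order '", order$id, "' lacks cox1; cannot normalize")
  genes <- order$genes
  strand <- order$strand
  if (strand[i] == "-") {
    genes <- rev(genes)
    strand <- rev(ifelse(strand == "+", "-", "+"))
    i <- match("cox1", genes)
  }
  rot <- c(seq_along(genes), seq_along(genes))[i:(i + length(genes) - 1L)]
  gene_order(order$id, genes[rot], strand[rot])
}

# signed neighbor context of every gene in a normalized order (circular)
.order_context <- function(order) {
  tok <- order_tokens(order)
  n <- length(tok)
  left <- tok[c(n, seq_len(n - 1L))]
  right <- tok[c(seq_len(n)[-1L], 1L)]
  data.frame(gene = order$genes, self = tok, left = left, right = right,
             stringsAsFactors = FALSE)
}

# do the two circular signed orders become identical after deleting `drop`?
.orders_equal_after_drop <- function(tok1, genes1, tok2, genes2, drop) {
  k1 <- tok1[!genes1 %in% drop]
  k2 <- tok2[!genes2 %in% drop]
  if (length(k1) != length(k2)) return(FALSE)
  if (!length(k1)) return(TRUE)
  anchor <- k1[1L]
  j <- match(anchor, k2)
  if (is.na(j)) return(FALSE)
  n <- length(k2)
  identical(k1, k2[c(j:n, seq_len(j - 1L))[seq_len(n)]])
}

#' Detect rearrangement events between two circular gene orders
#'
#' Finds the smallest set of genes whose removal makes the two normalized
#' circular signed orders identical; each such gene is one rearrangement
#' event, typed \code{reverse_transposition} when its orientation differs
#' between the normalized orders and \code{transposition} otherwise.  The
#' search is exhaustive over subsets of the candidate genes (those whose
#' signed neighbor context differs), smallest subset first with lexicographic
#' tie-breaking; genes whose orientation differs are necessarily part of any
#' solution and are fixed in advance.
#'
#' @param reference,query \code{gene_order}s over the same gene set.
#' @param max_events largest event set searched (default 12); beyond it a
#'   "complex rearrangement" error is raised.
#' @return data.frame of class \code{rearrangement_events}: gene, class, kind,
#'   source/destination junction columns (left/right neighbors), ordered by
#'   the gene's position in the query; zero rows when the orders agree.
#' @export
detect_events <- function(reference, query, max_events = 12L) {
  if (!setequal(reference$genes, query$genes))
    stop("gene sets differ between '", reference$id, "' and '", query$id, "'")
  r <- normalize_gene_order(reference)
  q <- normalize_gene_order(query)
  ctx_r <- .order_context(r)
  ctx_q <- .order_context(q)
  ctx_q <- ctx_q[match(ctx_r$gene, ctx_q$gene), ]
  differs <- ctx_r$self != ctx_q$self |
    ctx_r$left != ctx_q$left | ctx_r$right != ctx_q$right
  candidates <- sort(ctx_r$gene[differs])
  flipped <- sort(ctx_r$gene[ctx_r$self != ctx_q$self])
  empty <- data.frame(gene = character(), class = character(),
                      kind = character(),
                      src_left = character(), src_right = character(),
                      dst_left = character(), dst_right = character(),
                      stringsAsFactors = FALSE)
  class(empty) <- c("rearrangement_events", "data.frame")
  if (!length(candidates)) return(empty)
  tok_r <- order_tokens(r); tok_q <- order_tokens(q)
  free <- setdiff(candidates, flipped)
  solution <- NULL
  if (length(flipped) <= max_events) {
    max_extra <- min(length(free), max_events - length(flipped))
    for (k in 0:max_extra) {
      sets <- if (k == 0L) list(character(0)) else
        utils::combn(free, k, simplify = FALSE)
      hits <- Filter(function(extra)
        .orders_equal_after_drop(tok_r, r$genes, tok_q, q$genes,
                                 c(flipped, extra)), sets)
      if (length(hits)) {
        # among equal-cardinality solutions prefer the one moving the fewest
        # protein-coding genes (mitogenome rearrangements overwhelmingly move
        # tRNAs/rRNAs), then the lexicographically smallest set
        key <- vapply(hits, function(extra)
          sprintf("%02d|%s", sum(mito_gene_class(extra) == "PCG", na.rm = TRUE),
                  paste(sort(extra), collapse = ",")), "")
        solution <- c(flipped, hits[[order(key)[1L]]])
        break
      }
    }
  }
  if (is.null(solution))
    stop("complex rearrangement: no event set of size <= ", max_events,
         " explains the difference between '", reference$id, "' and '",
         query$id, "'")
  # order events by the moved gene's position in the query
  solution <- solution[order(match(solution, q$genes))]
  neigh <- function(ctx, g) unlist(ctx[match(g, ctx$gene), c("left", "right")])
  ev <- do.call(rbind, lapply(solution, function(g) {
    data.frame(gene = g, class = mito_gene_class(g),
               kind = if (g %in% flipped) "reverse_transposition"
                      else "transposition",
               src_left = neigh(ctx_r, g)[[1]], src_right = neigh(ctx_r, g)[[2]],
               dst_left = neigh(ctx_q, g)[[1]], dst_right = neigh(ctx_q, g)[[2]],
               stringsAsFactors = FALSE)
  }))
  rownames(ev) <- NULL
  class(ev) <- c("rearrangement_events", "data.frame")
  ev
}

#' Cluster genomes into gene-arrangement types
#'
#' Two genomes share an arrangement type iff their normalized circular signed
#' orders are identical.  Types are labelled A, B, C, ... in order of first
#' appearance in the input.
#'
#' @param orders list of \code{gene_order} objects.
#' @return data.frame of class \code{arrangement_types}: id, type, signature.
#' @export
cluster_types <- function(orders) {
  if (!length(orders)) stop("empty panel")
  sig <- vapply(orders, function(o)
    paste(order_tokens(normalize_gene_order(o)), collapse = " "), "")
  first <- !duplicated(sig)
  labels <- stats::setNames(LETTERS[seq_len(sum(first))], sig[first])
  out <- data.frame(id = vapply(orders, `[[`, "", "id"),
                    type = unname(labels[sig]), signature = unname(sig),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("arrangement_types", "data.frame")
  out
}

#' Census of rearranged genes across arrangement types
#'
#' Runs \code{\link{detect_events}} between one representative of the
#' reference type and one representative of every other type, and returns the
#' union of moved genes partitioned by gene class.
#'
#' @param orders list of \code{gene_order} objects.
#' @param reference_type type label used as the reference (default "A").
#' @param types optional precomputed \code{\link{cluster_types}} table.
#' @return list: \code{genes} (sorted union), \code{by_class} (list tRNA/rRNA/
#'   PCG), \code{events} (list of event tables per non-reference type).
#' @export
rearranged_gene_census <- function(orders, reference_type = "A",
                                   types = cluster_types(orders)) {
  if (!reference_type %in% types$type)
    stop("reference type '", reference_type, "' not present")
  ids <- vapply(orders, `[[`, "", "id")
  rep_of <- function(tp) orders[[match(types$id[types$type == tp][1L], ids)]]
  ref <- rep_of(reference_type)
  others <- setdiff(unique(types$type), reference_type)
  events <- lapply(others, function(tp) detect_events(ref, rep_of(tp)))
  names(events) <- others
  genes <- sort(unique(as.character(unlist(lapply(events, `[[`, "gene")))))
  cls <- mito_gene_class(genes)
  list(genes = genes,
       by_class = split(genes, factor(cls, c("PCG", "tRNA", "rRNA"))),
       events = events)
}

#' Apply scripted rearrangement events to a gene order
#'
#' Applies moves in sequence: each event removes one gene and reinserts it
#' immediately after the named \code{after} gene, flipping its orientation for
#' a reverse transposition.  Used both to build fixture arrangements and to
#' verify detected events by reconstruction.
#'
#' @param order a \code{gene_order}.
#' @param events list of events; each a list with \code{gene}, \code{kind}
#'   ("transposition"/"reverse_transposition"), \code{after} (left neighbor of
#'   the destination junction) and optional \code{before} (right neighbor,
#'   checked for adjacency when supplied).  A \code{rearrangement_events}
#'   table from \code{\link{detect_events}} is also accepted.
#' @param new_id id of the resulting order (default: input id).
#' @return rearranged \code{gene_order}.
#' @export
apply_scripted_rearrangements <- function(order, events, new_id = order$id) {
  if (inherits(events, "rearrangement_events")) {
    events <- lapply(seq_len(nrow(events)), function(i)
      list(gene = events$gene[i], kind = events$kind[i],
           after = substring(events$dst_left[i], 2)))
  }
  genes <- order$genes
  strand <- order$strand
  for (ev in events) {
    if (!all(c("gene", "kind", "after") %in% names(ev)))
      stop("event needs fields gene, kind, after")
    i <- match(ev$gene, genes)
    if (is.na(i)) stop("event references absent gene: ", ev$gene)
    g_strand <- strand[i]
    genes <- genes[-i]; strand <- strand[-i]
    j <- match(ev$after, genes)
    if (is.na(j))
      stop("destination junction ambiguous: gene '", ev$after,
           "' absent after earlier events")
    if (!is.null(ev$before)) {
      succ <- genes[if (j == length(genes)) 1L else j + 1L]
      if (succ != ev$before)
        stop("destination junction ambiguous: ", ev$after, "-", ev$before,
             " are not adjacent (current successor: ", succ, ")")
    }
    if (identical(ev$kind, "reverse_transposition"))
      g_strand <- if (g_strand == "+") "-" else "+"
    else if (!identical(ev$kind, "transposition"))
      stop("unknown event kind: ", ev$kind)
    genes <- append(genes, ev$gene, after = j)
    strand <- append(strand, g_strand, after = j)
  }
  gene_order(new_id, genes, strand)
}
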