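#' Construct an information table
#'
#' An information table S = (U, At, \{V_a\}, \{I_a\}) holds a finite universe
#' of objects U, a set of condition attributes At with an information function
#' assigning each object one value per attribute, and a single decision
#' column.  It is the basic container every other function in the package
#' consumes.
#'
#' @param data a data.frame of condition attributes (one row per object);
#'   columns are kept numeric when numeric, otherwise coerced to character.
#' @param decision vector of decision labels, one per object.
#' @param ids object identifiers; defaults to rownames or `O1..On`.
#' @param decision_name name of the decision column, used on output.
#' @return An object of class `information_table` with fields `ids`,
#'   `data`, `decision`, `decision_name` and (after [discretize()])
#'   `bin_edges`.
#' @examples
#' tab <- information_table(
#'   data.frame(Localization = c("M", "C"), Domains = c(0, 1)),
#'   decision = c("Yes", "No")
#' )
#' tab
#' @export
information_table <- function(data, decision, ids = NULL,
                              decision_name = "decision") {
  if (!is.data.frame(data)) stop("`data` must be a data.frame", call. = FALSE)
  n <- nrow(data)
  if (length(decision) != n)
    stop("`decision` must have one label per object", call. = FALSE)
  if (is.null(ids)) {
    ids <- if (!is.null(rownames(data)) &&
               !identical(rownames(data), as.character(seq_len(n))))
      rownames(data) else sprintf("O%d", seq_len(n))
  }
  ids <- as.character(ids)
  if (anyDuplicated(ids))
    stop("duplicate object id: ", ids[duplicated(ids)][1L], call. = FALSE)
  if (decision_name %in% names(data))
    stop("decision column '", decision_name,
         "' must not be among the attributes", call. = FALSE)
  data <- as.data.frame(lapply(data, function(col) {
    if (is.numeric(col)) col else as.character(col)
  }), stringsAsFactors = FALSE, optional = TRUE)
  names(data) <- names(data)
  rownames(data) <- NULL
  .check_complete(data, ids, decision)
  structure(
    list(ids = ids, data = data, decision = as.character(decision),
         decision_name = decision_name, bin_edges = NULL),
    class = "information_table"
  )
}

.check_complete <- function(data, ids, decision) {
  for (a in names(data)) {
    bad <- which(is.na(data[[a]]) | (is.character(data[[a]]) & data[[a]] == ""))
    if (length(bad))
      stop("missing value at row '", ids[bad[1L]], "', column '", a, "'",
           call. = FALSE)
  }
  bad <- which(is.na(decision) | decision == "")
  if (length(bad))
    stop("missing decision label at row '", ids[bad[1L]], "'", call. = FALSE)
  invisible(TRUE)
}

#' @export
print.information_table <- function(x, ...) {
  cat("Information table: ", length(x$ids), " objects, ",
      ncol(x$data), " attributes, decision '", x$decision_name, "'\n",
      sep = "")
  cat("Attributes:", paste(names(x$data), collapse = ", "), "\n")
  utils::str(table(x$decision))
  invisible(x)
}

#' @export
dim.information_table <- function(x) c(length(x$ids), ncol(x$data))

#' Attribute names of an information table
#' @param table an [information_table()].
#' @return Character vector of condition-attribute names.
#' @export
attributes_of <- function(table) {
  stopifnot(inherits(table, "information_table"))
  names(table$data)
}

#' Read an information table from a delimited file
#'
#' Parses a header-bearing CSV/TSV file into an [information_table()].  A
#' column parses as numeric when every entry does; otherwise it is kept
#' categorical.  Missing cells are rejected, naming the offending row and
#' column, because equivalence-class partitioning requires a total
#' information function.
#'
#' @param path file to read.
#' @param decision_col name of the decision column (required).
#' @param id_col optional name of the object-id column; when `NULL`, ids
#'   `O1..On` are assigned in file order.
#' @param sep field delimiter; `","` or `"\t"`.
#' @return An [information_table()]; attribute order follows the file.
#' @export
read_information_table <- function(path, decision_col, id_col = NULL,
                                   sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "\"",
                           fill = TRUE, na.strings = character())
  if (!decision_col %in% names(raw))
    stop("decision column '", decision_col, "' not found in ", path,
         call. = FALSE)
  ids <- NULL
  if (!is.null(id_col)) {
    if (!id_col %in% names(raw))
      stop("id column '", id_col, "' not found in ", path, call. = FALSE)
    ids <- raw[[id_col]]
    raw[[id_col]] <- NULL
  }
  decision <- raw[[decision_col]]
  raw[[decision_col]] <- NULL
  # numeric when the whole column parses as numbers
  for (a in names(raw)) {
    v <- raw[[a]]
    num <- suppressWarnings(as.numeric(v))
    if (!anyNA(num) && all(v != "")) raw[[a]] <- num
  }
  information_table(raw, decision, ids = ids, decision_name = decision_col)
}

#' Restrict an information table to a subset of attributes
#'
#' Evolving information is modelled by restricting the table to the
#' attributes available at a given time; objects and the decision column are
#' untouched.  Restriction to the empty set is allowed and yields a single
#' all-object equivalence class downstream.
#'
#' @param table an [information_table()].
#' @param attrs character vector of attribute names, a subset of
#'   `attributes_of(table)` (order preserved from the original table).
#' @return An [information_table()] over the same objects.
#' @export
restrict_attributes <- function(table, attrs) {
  stopifnot(inherits(table, "information_table"))
  unknown <- setdiff(attrs, names(table$data))
  if (length(unknown))
    stop("unknown attribute(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  keep <- intersect(names(table$data), attrs)  # original order
  out <- table
  out$data <- table$data[, keep, drop = FALSE]
  if (!is.null(table$bin_edges)) out$bin_edges <- table$bin_edges[
    intersect(names(table$bin_edges), keep)]
  out
}

#' Subset an information table to a set of objects
#'
#' @param table an [information_table()].
#' @param ids object identifiers to keep (order of `ids` is respected).
#' @return An [information_table()] over the requested objects.
#' @export
subset_objects <- function(table, ids) {
  stopifnot(inherits(table, "information_table"))
  idx <- match(ids, table$ids)
  if (anyNA(idx))
    stop("unknown object id(s): ", paste(ids[is.na(idx)], collapse = ", "),
         call. = FALSE)
  out <- table
  out$ids <- table$ids[idx]
  out$data <- table$data[idx, , drop = FALSE]
  rownames(out$data) <- NULL
  out$decision <- table$decision[idx]
  out
}

#' Discretize numeric attributes into categorical bins
#'
#' Equivalence classes require categorical values, so continuous features
#' (counts, weights) are binned before partitioning.  Bin edges are learned
#' from the table at hand and recorded in the result's `bin_edges` field so
#' the same edges can be applied to held-out objects with
#' [apply_bin_edges()]; held-out values outside the training range clamp to
#' the first/last bin.
#'
#' @param table an [information_table()].
#' @param policy `"equal_frequency"` (default; quantile edges, robust to
#'   skewed count data), `"equal_width"`, or `"none"`.
#' @param bins maximum number of bins per numeric attribute (>= 1); constant
#'   columns collapse to a single bin without error.
#' @return An [information_table()] whose numeric attributes are replaced by
#'   labels `b1..bk`, with `bin_edges` recording the interior cut points.
#' @export
discretize <- function(table, policy = c("equal_frequency", "equal_width",
                                         "none"), bins = 5) {
  stopifnot(inherits(table, "information_table"))
  policy <- match.arg(policy)
  if (bins < 1) stop("`bins` must be >= 1", call. = FALSE)
  if (policy == "none") return(table)
  edges <- list()
  out <- table
  for (a in names(table$data)) {
    v <- table$data[[a]]
    if (!is.numeric(v)) next
    cuts <- if (policy == "equal_width") {
      rng <- range(v)
      if (diff(rng) == 0) numeric(0)
      else seq(rng[1L], rng[2L], length.out = bins + 1L)[-c(1L, bins + 1L)]
    } else {
      q <- stats::quantile(v, probs = seq_len(bins - 1L) / bins,
                           type = 1, names = FALSE)
      unique(q[q > min(v) & q < max(v)])
    }
    edges[[a]] <- cuts
    out$data[[a]] <- .bin_label(v, cuts)
  }
  out$bin_edges <- edges
  out
}

# bin by interior cut points: value <= cuts[k] -> bin k; above all -> top bin
.bin_label <- function(v, cuts) {
  idx <- findInterval(v, cuts, left.open = TRUE) + 1L
  paste0("b", idx)
}

#' Apply previously learned bin edges to a table
#'
#' @param table an [information_table()] with raw numeric attributes.
#' @param edges the `bin_edges` field of a table returned by [discretize()].
#' @return The table with numeric attributes binned on the supplied edges.
#' @export
apply_bin_edges <- function(table, edges) {
  stopifnot(inherits(table, "information_table"))
  out <- table
  for (a in names(edges)) {
    if (!a %in% names(table$data)) next
    if (is.numeric(table$data[[a]]))
      out$data[[a]] <- .bin_label(table$data[[a]], edges[[a]])
  }
  out$bin_edges <- edges
  out
}

#' Extract a concept from the decision column
#'
#' A concept C is the subset of the universe carrying a target decision
#' label (e.g. proteins annotated with a given function); its complement
#' C^c is the rest of the universe.
#'
#' @param table an [information_table()].
#' @param label the decision value defining membership.
#' @return Object of class `concept`: list with `members`, `label`,
#'   `universe`.
#' @export
concept_from_decision <- function(table, label) {
  stopifnot(inherits(table, "information_table"))
  members <- table$ids[table$decision == label]
  if (!length(members))
    warning("label '", label, "' does not occur in the decision column; ",
            "concept is empty", call. = FALSE)
  structure(list(members = members, label = as.character(label),
                 universe = table$ids),
            class = "concept")
}

#' @export
print.concept <- function(x, ...) {
  cat("Concept '", x$label, "': ", length(x$members), " of ",
      length(x$universe), " objects\n", sep = "")
  invisible(x)
}

# internal: per-object signature strings for an attribute subset
.signatures <- function(table, attrs) {
  if (!length(attrs)) return(rep("", length(table$ids)))
  cols <- lapply(attrs, function(a) {
    v <- table$data[[a]]
    if (is.numeric(v)) as.character(v) else v
  })
  do.call(paste, c(cols, sep = "\x1f"))
}

#' Partition a universe into equivalence classes
#'
#' Two objects are indiscernible under an attribute set A when they share
#' the same value on every attribute in A; the equivalence classes of this
#' relation partition the universe.  Blocks are ordered lexicographically by
#' their value signature so output is reproducible regardless of row order.
#'
#' @param table an [information_table()].
#' @param attrs attribute subset (possibly empty: one block equal to U).
#' @return Object of class `partition`: list with `blocks` (each a list with
#'   `members` and named `signature`), `attribute_set`, `universe`.
#' @examples
#' tab <- table1_fixture()
#' compute_partition(tab, "Localization")
#' @export
compute_partition <- function(table, attrs = attributes_of(table)) {
  stopifnot(inherits(table, "information_table"))
  unknown <- setdiff(attrs, names(table$data))
  if (length(unknown))
    stop("unknown attribute(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  attrs <- intersect(names(table$data), attrs)
  sig <- .signatures(table, attrs)
  groups <- split(table$ids, sig)
  groups <- groups[order(names(groups), method = "radix")]
  blocks <- lapply(seq_along(groups), function(i) {
    vals <- strsplit(names(groups)[i], "\x1f", fixed = TRUE)[[1L]]
    if (!length(attrs)) vals <- character(0)
    names(vals) <- attrs
    list(members = groups[[i]], signature = vals)
  })
  structure(list(blocks = blocks, attribute_set = attrs,
                 universe = table$ids),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat("Partition on {", paste(x$attribute_set, collapse = ", "), "}: ",
      length(x$blocks), " equivalence classes over ",
      length(x$universe), " objects\n", sep = "")
  for (b in x$blocks[seq_len(min(10L, length(x$blocks)))])
    cat("  [", paste(b$signature, collapse = ", "), "] -> {",
        paste(b$members, collapse = ", "), "}\n", sep = "")
  if (length(x$blocks) > 10L) cat("  ...\n")
  invisible(x)
}

#' Conditional probability of a concept given an equivalence class
#'
#' P(C | \[x\]) = |\[x\] intersect C| / |\[x\]|, the fraction of a block's
#' members that belong to the concept.
#'
#' @param block a block of a [compute_partition()] result (list with a
#'   `members` field), or a plain character vector of object ids.
#' @param concept a [concept_from_decision()] result.
#' @return Probability in \[0, 1\].
#' @export
conditional_probability <- function(block, concept) {
  members <- if (is.list(block)) block$members else block
  if (!length(members)) stop("conditional probability of an empty block is
 undefined", call. = FALSE)
  sum(members %in% concept$members) / length(members)
}

# internal fast path: one row per block with size, concept count, P(C|[x]).
# Used by every learner; avoids rebuilding the block list structure.
.block_stats <- function(table, attrs, concept) {
  sig <- .signatures(table, attrs)
  in_c <- table$ids %in% concept$members
  size <- tapply(in_c, sig, length)
  npos <- tapply(in_c, sig, sum)
  ord <- order(names(size), method = "radix")
  data.frame(signature = names(size)[ord],
             size = as.integer(size[ord]),
             n_concept = as.integer(npos[ord]),
             prob = as.numeric(npos[ord] / size[ord]),
             stringsAsFactors = FALSE)
}
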