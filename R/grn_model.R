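# Signed directed regulatory network: construction, I/O, validation,
# degree queries.

ROLE_MAP <- c(
  "activation" = 1L, "activator" = 1L, "+" = 1L, "+1" = 1L, "1" = 1L,
  "repression" = -1L, "repressor" = -1L, "-" = -1L, "−" = -1L,
  "-1" = -1L, "−1" = -1L
)

#' Construct a signed regulatory network
#'
#' A `regulatory_network` holds a set of gene identifiers and a list of signed
#' directed edges (regulator -> target), with sign `+1` for activation and
#' `-1` for repression. Gene identifiers are opaque, case-sensitive strings;
#' no locus-tag normalization is performed, so identifiers must match those
#' used in the expression compendium exactly.
#'
#' Duplicate (regulator, target) rows with the same sign are silently
#' deduplicated. Rows with conflicting signs for the same pair are an error by
#' default because the sign-consistency model is undefined for dual-role
#' edges; with `permissive = TRUE` such pairs are removed from the edge table
#' and kept in the `quarantined` field so downstream reports can count them.
#' Self-loops (autoregulation) are retained and flagged in the edge table.
#'
#' @param edges data.frame with columns `regulator`, `target`, `sign`
#'   (integer, +1 or -1). Extra columns (e.g. `weight`) are carried along.
#' @param nodes optional character vector of node ids; regulators and targets
#'   are always included.
#' @param operon_map optional named character vector mapping target gene ids
#'   to operon ids.
#' @param permissive logical; quarantine sign-conflicting duplicate pairs
#'   instead of aborting.
#' @return An object of class `regulatory_network`: a list with `edges`
#'   (data.frame: regulator, target, sign, self_loop, ...), `nodes`
#'   (character), `operon_map`, and `quarantined` (data.frame of excluded
#'   dual-role pairs, possibly empty).
#' @examples
#' net <- regulatory_network(data.frame(
#'   regulator = c("A", "A", "B"),
#'   target = c("B", "C", "C"),
#'   sign = c(1L, -1L, 1L)
#' ))
#' net
#' @export
regulatory_network <- function(edges, nodes = NULL, operon_map = NULL,
                               permissive = FALSE) {
  stopifnot(is.data.frame(edges))
  if (nrow(edges) == 0L) {
    edges <- data.frame(regulator = character(), target = character(),
                        sign = integer(), self_loop = logical(),
                        stringsAsFactors = FALSE)
  } else {
    needed <- c("regulator", "target", "sign")
    missing_cols <- setdiff(needed, names(edges))
    if (length(missing_cols) > 0L) {
      stop("edge table lacks column(s): ", paste(missing_cols, collapse = ", "))
    }
    edges$regulator <- as.character(edges$regulator)
    edges$target <- as.character(edges$target)
    if (!all(edges$sign %in% c(-1L, 1L))) {
      bad <- which(!(edges$sign %in% c(-1L, 1L)))
      stop("edge sign must be +1 or -1; offending row(s): ",
           paste(utils::head(bad, 5L), collapse = ", "))
    }
    edges$sign <- as.integer(edges$sign)
  }

  quarantined <- edges[0L, , drop = FALSE]
  if (nrow(edges) > 0L) {
    # same-sign duplicates collapse silently
    edges <- edges[!duplicated(edges[c("regulator", "target", "sign")]), ,
                   drop = FALSE]
    pair <- paste(edges$regulator, edges$target, sep = "\r")
    dup <- pair[duplicated(pair)]
    if (length(dup) > 0L) {
      conflicted <- unique(dup)
      shown <- vapply(strsplit(conflicted, "\r", fixed = TRUE),
                      function(p) sprintf("(%s, %s)", p[1L], p[2L]), "")
      if (!permissive) {
        stop("conflicting signs for regulator-target pair(s): ",
             paste(shown, collapse = ", "),
             " (use permissive = TRUE to quarantine them)")
      }
      keep <- !(pair %in% conflicted)
      quarantined <- edges[!keep, , drop = FALSE]
      edges <- edges[keep, , drop = FALSE]
    }
    edges$self_loop <- edges$regulator == edges$target
    rownames(edges) <- NULL
  }

  nodes <- sort(unique(c(as.character(nodes), edges$regulator, edges$target)))
  if (!is.null(operon_map)) {
    stopifnot(!is.null(names(operon_map)))
    operon_map <- vapply(operon_map, as.character, "")
  }
  structure(
    list(edges = edges, nodes = nodes, operon_map = operon_map,
         quarantined = quarantined),
    class = "regulatory_network"
  )
}

#' @export
print.regulatory_network <- function(x, ...) {
  n_act <- sum(x$edges$sign == 1L)
  n_rep <- sum(x$edges$sign == -1L)
  cat(sprintf(
    "regulatory_network: %d nodes, %d edges (%d activation, %d repression)\n",
    length(x$nodes), nrow(x$edges), n_act, n_rep))
  if (any(x$edges$self_loop)) {
    cat(sprintf("  self-loops: %d\n", sum(x$edges$self_loop)))
  }
  if (nrow(x$quarantined) > 0L) {
    cat(sprintf("  quarantined dual-role rows: %d\n", nrow(x$quarantined)))
  }
  invisible(x)
}

#' Read a signed edge list from a TSV or SIF file
#'
#' The TSV dialect has a header line and columns
#' `regulator<TAB>target<TAB>role` with an optional 4th column `operon`
#' (operon id of the target). The SIF dialect is headerless
#' `regulator<TAB>role<TAB>target`. Lines starting with `#` are ignored.
#' Role strings are mapped case-insensitively: activation/activator/+ become
#' `+1`, repression/repressor/- become `-1`. An unknown role string is a
#' parse error naming the offending line.
#'
#' @param path file path.
#' @param dialect `"tsv"` (default) or `"sif"`.
#' @param permissive passed to [regulatory_network()]: quarantine dual-role
#'   pairs instead of aborting.
#' @return A validated [regulatory_network()].
#' @export
read_edge_list <- function(path, dialect = c("tsv", "sif"),
                           permissive = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (dialect == "tsv") {
    if (length(lines) == 0L) stop("edge list has no header line: ", path)
    line_no <- line_no[-1L]
    lines <- lines[-1L]
  }
  if (length(lines) == 0L) {
    return(regulatory_network(data.frame(regulator = character(),
                                         target = character(),
                                         sign = integer())))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_min <- 3L
  short <- which(lengths(fields) < n_min)
  if (length(short) > 0L) {
    stop(sprintf("line %d of %s has fewer than 3 tab-separated fields",
                 line_no[short[1L]], path))
  }
  if (dialect == "tsv") {
    reg <- vapply(fields, `[[`, "", 1L)
    tgt <- vapply(fields, `[[`, "", 2L)
    role <- vapply(fields, `[[`, "", 3L)
    operon <- vapply(fields, function(f) if (length(f) >= 4L) f[[4L]] else "",
                     "")
  } else {
    reg <- vapply(fields, `[[`, "", 1L)
    role <- vapply(fields, `[[`, "", 2L)
    tgt <- vapply(fields, `[[`, "", 3L)
    operon <- rep("", length(fields))
  }
  sign <- ROLE_MAP[tolower(trimws(role))]
  if (anyNA(sign)) {
    bad <- which(is.na(sign))[1L]
    stop(sprintf("unknown role %s on line %d of %s",
                 dQuote(role[bad]), line_no[bad], path))
  }
  operon_map <- NULL
  has_op <- nzchar(operon)
  if (any(has_op)) {
    operon_map <- operon[has_op]
    names(operon_map) <- tgt[has_op]
    operon_map <- operon_map[!duplicated(names(operon_map))]
  }
  regulatory_network(
    data.frame(regulator = reg, target = tgt, sign = unname(sign),
               stringsAsFactors = FALSE),
    operon_map = operon_map, permissive = permissive
  )
}

#' Write a network back to an edge-list TSV
#'
#' Inverse of [read_edge_list()] for the TSV dialect; reading the written
#' file reproduces the validated network.
#'
#' @param net a [regulatory_network()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "regulatory_network"))
  role <- ifelse(net$edges$sign == 1L, "activation", "repression")
  df <- data.frame(regulator = net$edges$regulator,
                   target = net$edges$target, role = role)
  if (!is.null(net$operon_map)) {
    df$operon <- ifelse(df$target %in% names(net$operon_map),
                        net$operon_map[df$target], "")
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-node in- and out-degrees
#'
#' @param net a [regulatory_network()].
#' @return data.frame with columns `node`, `out_degree` (targets regulated),
#'   `in_degree` (regulators). Degree totals each equal the edge count; this
#'   is the profile that degree-preserving rewiring keeps fixed.
#' @export
degree_profile <- function(net) {
  stopifnot(inherits(net, "regulatory_network"))
  out_d <- table(factor(net$edges$regulator, levels = net$nodes))
  in_d <- table(factor(net$edges$target, levels = net$nodes))
  data.frame(node = net$nodes,
             out_degree = as.integer(out_d),
             in_degree = as.integer(in_d),
             stringsAsFactors = FALSE)
}

#' Targets regulated by exactly one transcription factor
#'
#' Multi-regulator targets can be inconsistent with one regulator while
#' obeying another, so single-regulator targets are the unambiguous subset
#' for correlation and consistency splits.
#'
#' @param net a [regulatory_network()].
#' @return character vector of target gene ids with in-degree 1.
#' @export
single_regulator_targets <- function(net) {
  stopifnot(inherits(net, "regulatory_network"))
  tab <- table(net$edges$target)
  sort(as.character(names(tab)[tab == 1L]))
}

#' Transcription factors of a network
#'
#' @param net a [regulatory_network()].
#' @return character vector of nodes with out-degree >= 1.
#' @export
transcription_factors <- function(net) {
  stopifnot(inherits(net, "regulatory_network"))
  sort(unique(net$edges$regulator))
}
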