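#' Gene set collections and the GMT format
#'
#' A gene set collection is an ordered list of sets, each a character vector
#' of unique member ids, with one-line descriptions. The on-disk format is the
#' Broad 3+ column GMT dialect (tab-separated: set name, description,
#' members), the de-facto standard consumed by GSEA implementations.
#'
#' @param sets named list of character vectors (member ids per set).
#' @param descriptions optional character vector, one per set (default "na").
#' @return object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  ps_assert(is.list(sets) &&
              (length(sets) == 0 ||
                 (!is.null(names(sets)) && all(nzchar(names(sets))))),
            "sets must be a named list")
  if (length(sets) == 0) names(sets) <- character(0)
  ps_assert(!anyDuplicated(names(sets)), "duplicate set names")
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  ps_assert(length(descriptions) == length(sets),
            "one description per set required")
  for (nm in names(sets)) {
    members <- sets[[nm]]
    ps_assert(length(members) >= 1, "empty member list in set ", nm)
    if (anyDuplicated(members)) {
      warning("duplicate member ids dropped in set ", nm, call. = FALSE)
      sets[[nm]] <- unique(members)
    }
  }
  structure(list(sets = sets, descriptions = stats::setNames(descriptions,
                                                             names(sets))),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  if (length(x$sets) == 0) {
    cat("gene_set_collection: empty\n")
  } else {
    sizes <- lengths(x$sets)
    cat(sprintf("gene_set_collection: %d sets, sizes %d-%d\n",
                length(x$sets), min(sizes), max(sizes)))
  }
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Read a GMT file
#'
#' @param path GMT file; each line must have at least 3 tab-separated fields
#'   (name, description, one or more member ids). Duplicate members within a
#'   set are dropped with a warning; a duplicate set name or a short line is
#'   an error naming the line number.
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  ps_assert(file.exists(path), "GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lineno <- which(nzchar(lines))
  fields <- strsplit(lines[lineno], "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short) > 0) {
    ps_stop(sprintf("GMT parse error: line %d has %d field(s); need >= 3",
                    lineno[short[1]], lengths(fields)[short[1]]))
  }
  nms <- vapply(fields, `[[`, "", 1)
  if (anyDuplicated(nms)) {
    ps_stop("duplicate set name in GMT: ", nms[duplicated(nms)][1])
  }
  descs <- vapply(fields, `[[`, "", 2)
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- nms
  gene_set_collection(sets, descs)
}

#' Write a GMT file
#'
#' Inverse of [read_gmt()]: write then read returns the identical collection.
#' @param collection a [gene_set_collection()].
#' @param path output path.
#' @export
write_gmt <- function(collection, path) {
  ps_assert(inherits(collection, "gene_set_collection"),
            "collection must be a gene_set_collection")
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$descriptions[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
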