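#' Gene-set collections
#'
#' A gene-set collection is a named list of character vectors (set members)
#' with a parallel `description` attribute, mirroring the GMT format. Set
#' names must be unique, every set non-empty, and members unique within a
#' set.
#'
#' @param sets Named list of character vectors.
#' @param descriptions Optional character vector of per-set descriptions
#'   (recycled `"na"` when absent).
#' @return An object of class `gene_set_collection`.
#' @seealso [read_gmt()], [write_gmt()]
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (!is.list(sets) || length(sets) == 0L) {
    abort("a gene-set collection needs at least one set")
  }
  nm <- names(sets)
  if (is.null(nm) || anyNA(nm) || any(nm == "")) {
    abort("every gene set must be named")
  }
  if (anyDuplicated(nm)) {
    abort(sprintf("duplicate gene-set name(s): %s",
                  paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  }
  sets <- lapply(sets, as.character)
  if (any(lengths(sets) == 0L)) {
    abort(sprintf("empty gene set(s): %s",
                  paste(nm[lengths(sets) == 0L], collapse = ", ")))
  }
  dup_in <- vapply(sets, anyDuplicated, integer(1L)) > 0L
  if (any(dup_in)) {
    abort(sprintf("duplicate members within set(s): %s",
                  paste(nm[dup_in], collapse = ", ")))
  }
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  if (length(descriptions) != length(sets)) {
    abort("descriptions must match the number of sets")
  }
  structure(sets, descriptions = setNames(as.character(descriptions), nm),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets, member counts %d-%d\n",
              length(x), min(lengths(x)), max(lengths(x))))
  shown <- head(names(x), 5L)
  for (nm in shown) {
    cat(sprintf("  %s (%d): %s%s\n", nm, length(x[[nm]]),
                paste(head(x[[nm]], 4L), collapse = ", "),
                if (length(x[[nm]]) > 4L) ", ..." else ""))
  }
  if (length(x) > 5L) cat(sprintf("  ... and %d more\n", length(x) - 5L))
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-delimited as
#' `name<TAB>description<TAB>member1<TAB>member2...`. Duplicate members
#' within one line are dropped with a warning; trailing empty fields and a
#' trailing newline are tolerated.
#'
#' @param path Path to a GMT file.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  keep <- !(seq_along(lines) == length(lines) & lines == "")
  lines <- lines[keep]
  if (length(lines) == 0L) abort(sprintf("%s: empty GMT file", path))
  sets <- vector("list", length(lines))
  descs <- character(length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    fields <- fields[!(seq_along(fields) > 2L & fields == "")]
    if (length(fields) < 3L) {
      abort(sprintf("%s: line %d has %d field(s); GMT needs name, description and >=1 member",
                    path, i, length(fields)))
    }
    members <- fields[-(1:2)]
    if (anyDuplicated(members)) {
      warn(sprintf("%s: line %d ('%s'): %d duplicate member(s) dropped",
                   path, i, fields[1L], sum(duplicated(members))))
      members <- unique(members)
    }
    nms[i] <- fields[1L]
    descs[i] <- fields[2L]
    sets[[i]] <- members
  }
  if (anyDuplicated(nms)) {
    abort(sprintf("%s: duplicate set name(s): %s", path,
                  paste(unique(nms[duplicated(nms)]), collapse = ", ")))
  }
  gene_set_collection(setNames(sets, nms), descs)
}

#' @rdname read_gmt
#' @param x A `gene_set_collection`.
#' @export
write_gmt <- function(x, path) {
  stopifnot(inherits(x, "gene_set_collection"))
  descs <- attr(x, "descriptions")
  lines <- vapply(names(x), function(nm) {
    paste(c(nm, descs[[nm]], x[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}
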