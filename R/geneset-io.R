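#' Construct a PathwaySet
#'
#' @param sets named list of character vectors of gene ids (one per pathway)
#' @param descriptions optional character vector of free-text descriptions,
#'   recycled to `""` when absent
#' @param universe optional character vector of measurable gene ids
#' @return a [PathwaySet-class]
#' @examples
#' ps <- PathwaySet(list(P1 = c("g1", "g2", "g3"), P2 = c("g2", "g4")))
#' pathwaySizes(ps)
#' @export
PathwaySet <- function(sets, descriptions = NULL, universe = NULL) {
    sets <- as.list(sets)
    if (is.null(descriptions)) {
        descriptions <- rep("", length(sets))
    }
    descriptions <- as.character(descriptions)
    names(descriptions) <- names(sets)
    if (!is.null(universe)) universe <- unique(as.character(universe))
    new("PathwaySet", sets = sets, descriptions = descriptions,
        universe = universe)
}

#' @describeIn PathwaySet number of gene sets in the collection
#' @param x,object a `PathwaySet`
#' @export
setMethod("length", "PathwaySet", function(x) length(x@sets))

#' Accessors for PathwaySet
#'
#' `pathwayIds()` returns the set ids, `pathwayMembers()` the named list of
#' member vectors, `pathwayDescriptions()` the descriptions, `pathwaySizes()`
#' the effective sizes (after intersection with the universe when one is
#' set), and `geneUniverse()` the universe (or `NULL`).
#'
#' @param x a [PathwaySet-class]
#' @return see individual descriptions
#' @name pathway-accessors
NULL

#' @rdname pathway-accessors
#' @export
pathwayIds <- function(x) names(x@sets)

#' @rdname pathway-accessors
#' @export
pathwayMembers <- function(x) x@sets

#' @rdname pathway-accessors
#' @export
pathwayDescriptions <- function(x) x@descriptions

#' @rdname pathway-accessors
#' @export
geneUniverse <- function(x) x@universe

#' @rdname pathway-accessors
#' @export
pathwaySizes <- function(x) {
    if (is.null(x@universe)) {
        vapply(x@sets, length, integer(1L))
    } else {
        vapply(x@sets, function(s) sum(s %in% x@universe), integer(1L))
    }
}

setMethod("show", "PathwaySet", function(object) {
    cat("PathwaySet with", length(object@sets), "gene set(s)\n")
    if (!is.null(object@universe))
        cat("  universe:", length(object@universe), "genes\n")
    n <- min(length(object@sets), 5L)
    if (n > 0L) {
        sz <- pathwaySizes(object)
        for (i in seq_len(n))
            cat(sprintf("  %s (%d genes)\n", names(object@sets)[i], sz[i]))
        if (length(object@sets) > n) cat("  ...\n")
    }
    invisible(NULL)
})

#' Read a gene-set collection from a GMT file
#'
#' GMT is tab-separated with one gene set per line: set id, description, then
#' one field per member gene. The second field is always a description, never
#' a gene. Duplicate genes within a line are removed with a warning;
#' duplicate set ids across lines are an error.
#'
#' @param path path to a GMT file
#' @return a [PathwaySet-class] (universe unset)
#' @examples
#' gmt <- tempfile(fileext = ".gmt")
#' writeLines("P1\tdemo pathway\tg1\tg2\tg3", gmt)
#' readGMT(gmt)
#' @export
readGMT <- function(path) {
    if (!file.exists(path)) stop("GMT file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    sets <- list()
    descs <- character()
    for (i in seq_along(lines)) {
        fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
        if (length(fields) < 3L)
            stop(sprintf(
                "malformed GMT line %d: expected at least 3 tab-separated fields, got %d",
                i, length(fields)))
        id <- fields[[1L]]
        if (id %in% names(sets))
            stop(sprintf("duplicate set id '%s' at GMT line %d", id, i))
        genes <- fields[-c(1L, 2L)]
        genes <- genes[nzchar(genes)]
        if (anyDuplicated(genes)) {
            warning(sprintf(
                "GMT line %d (set '%s'): duplicate gene ids removed", i, id))
            genes <- unique(genes)
        }
        sets[[id]] <- genes
        descs[[id]] <- fields[[2L]]
    }
    PathwaySet(sets, descs)
}

#' Write a gene-set collection to a GMT file
#'
#' Round-trips with [readGMT()].
#'
#' @param x a [PathwaySet-class]
#' @param path output file path
#' @return `path`, invisibly
#' @export
writeGMT <- function(x, path) {
    stopifnot(is(x, "PathwaySet"))
    lines <- vapply(seq_along(x@sets), function(i) {
        paste(c(names(x@sets)[i], x@descriptions[[i]], x@sets[[i]]),
              collapse = "\t")
    }, character(1L))
    writeLines(lines, path)
    invisible(path)
}

#' Filter gene sets by effective size against a gene universe
#'
#' Intersects every set with the universe of measurable genes and keeps the
#' sets whose effective size s = |members n universe| satisfies
#' `minSize <= s <= maxSize`. The defaults (15 and 500) drop pathways that
#' are too small to be meaningful or too general to be informative. Members
#' are replaced by the intersection, so every retained member is measurable;
#' the input object is not modified. The filter is idempotent.
#'
#' @param x a [PathwaySet-class]
#' @param universe character vector of measurable gene ids
#' @param minSize smallest effective size kept (>= 1)
#' @param maxSize largest effective size kept (>= `minSize`)
#' @return a new [PathwaySet-class] with `universe` recorded
#' @examples
#' ps <- PathwaySet(list(A = paste0("g", 1:20), B = paste0("g", 1:3)))
#' filterPathways(ps, paste0("g", 1:25), minSize = 5, maxSize = 500)
#' @export
filterPathways <- function(x, universe, minSize = 15L, maxSize = 500L) {
    stopifnot(is(x, "PathwaySet"))
    universe <- unique(as.character(universe))
    if (length(universe) == 0L) stop("universe must not be empty")
    if (minSize < 1L) stop("minSize must be >= 1")
    if (maxSize < minSize) stop("maxSize must be >= minSize")
    trimmed <- lapply(x@sets, function(s) s[s %in% universe])
    sizes <- vapply(trimmed, length, integer(1L))
    keep <- sizes >= minSize & sizes <= maxSize
    PathwaySet(trimmed[keep], x@descriptions[keep], universe = universe)
}
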