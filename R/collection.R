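# Named element sets with a background universe, plus readers/writers for the
# standard set-list formats (GMT, one-set-per-column tables).

#' Construct a collection of named sets over a background population
#'
#' @param sets Named list of character vectors of element identifiers.
#'   Identifiers are whitespace-trimmed; duplicates within a set are removed
#'   with a warning.  Comparison is exact (case-sensitive) string equality.
#' @param background Either a single integer — the size of the background
#'   population the sets were drawn from — or a character vector listing the
#'   universe explicitly.  May be left `NULL` at construction and supplied
#'   later (required before testing).
#' @param drop_foreign With an explicit universe, set members absent from it
#'   are an error by default; `drop_foreign = TRUE` removes them with a
#'   warning instead.
#' @return An object of class `"set_collection"`: a list with `sets` (named
#'   list of unique identifiers), `background_size` (integer or `NA`) and
#'   `universe` (character or `NULL`).
#' @examples
#' sc <- set_collection(list(A = c("a", "b", "c"), B = c("b", "c", "d")),
#'                      background = 10)
#' count_overlap(sc, c("A", "B"))
#' @export
set_collection <- function(sets, background = NULL, drop_foreign = FALSE) {
  if (!is.list(sets) || length(sets) < 1L) stop("'sets' must be a non-empty list")
  nm <- names(sets)
  if (is.null(nm) || any(!nzchar(nm))) stop("every set must be named")
  if (anyDuplicated(nm)) stop("duplicated set names: ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  sets <- lapply(sets, function(s) {
    s <- trimws(as.character(s))
    s <- s[nzchar(s)]
    s
  })
  for (i in seq_along(sets)) {
    if (anyDuplicated(sets[[i]])) {
      warning("set '", nm[i], "': ", sum(duplicated(sets[[i]])),
              " duplicated identifier(s) removed", call. = FALSE)
      sets[[i]] <- unique(sets[[i]])
    }
  }
  universe <- NULL
  bg_size <- NA_integer_
  if (!is.null(background)) {
    if (is.numeric(background) && length(background) == 1L) {
      if (background != round(background) || background < 1) {
        stop("background size must be a positive integer")
      }
      bg_size <- as.integer(background)
    } else if (is.character(background)) {
      universe <- unique(trimws(background))
      universe <- universe[nzchar(universe)]
      bg_size <- length(universe)
      for (i in seq_along(sets)) {
        foreign <- setdiff(sets[[i]], universe)
        if (length(foreign)) {
          if (drop_foreign) {
            warning("set '", nm[i], "': dropping ", length(foreign),
                    " identifier(s) absent from the background universe",
                    call. = FALSE)
            sets[[i]] <- intersect(sets[[i]], universe)
          } else {
            stop("set '", nm[i], "' contains identifiers absent from the ",
                 "background universe (e.g. '", foreign[1L], "'); ",
                 "use drop_foreign = TRUE to remove them")
          }
        }
      }
    } else {
      stop("'background' must be a single integer size or a character universe")
    }
    union_size <- length(unique(unlist(sets, use.names = FALSE)))
    if (bg_size < union_size) {
      stop("background size (", bg_size, ") is smaller than the union of the sets (",
           union_size, ")")
    }
  }
  structure(list(sets = sets, background_size = bg_size, universe = universe),
            class = "set_collection")
}

#' @export
print.set_collection <- function(x, ...) {
  cat(sprintf("Collection of %d sets", length(x$sets)))
  if (!is.na(x$background_size)) {
    cat(sprintf(" over a background of %d elements%s", x$background_size,
                if (is.null(x$universe)) " (size only)" else " (explicit universe)"))
  } else {
    cat(" (background not yet specified)")
  }
  cat("\n")
  sz <- vapply(x$sets, length, 1L)
  for (i in seq_along(sz)) cat(sprintf("  %s: %d elements\n", names(sz)[i], sz[i]))
  invisible(x)
}

set_sizes <- function(collection) vapply(collection$sets, length, 1L)

#' Read gene-set files
#'
#' `read_gmt` parses the Broad GMT dialect: one set per line, tab-separated
#' fields `name`, `description`, then member identifiers.  `read_set_columns`
#' parses a table with one set per column (header row = set names, ragged
#' columns allowed, empty cells ignored); the delimiter is taken from the file
#' extension (`.csv` = comma, otherwise tab) unless given.
#'
#' Neither format carries a background population, so `background` of the
#' result is unset; supply it via the `background` argument or later through
#' [set_collection()].
#'
#' @param path Path to the file.
#' @param background Optional background (integer size or character universe)
#'   forwarded to [set_collection()].
#' @param sep Field separator for `read_set_columns`; `NULL` (default) picks
#'   it from the extension.
#' @return A [set_collection()].
#' @export
read_gmt <- function(path, background = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file: ", path)
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop("malformed GMT line ", i, ": expected at least 3 tab-separated fields")
    }
    nm <- trimws(fields[1L])
    if (nm %in% names(sets)) stop("malformed GMT line ", i, ": duplicated set name '", nm, "'")
    sets[[nm]] <- fields[-(1:2)]
  }
  set_collection(sets, background = background)
}

#' @rdname read_gmt
#' @export
read_set_columns <- function(path, background = NULL, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, sep = sep, header = FALSE,
                           colClasses = "character", fill = TRUE,
                           quote = "\"", stringsAsFactors = FALSE)
  if (nrow(tab) < 1L) stop("empty table: ", path)
  header <- trimws(as.character(tab[1L, ]))
  if (any(!nzchar(header))) stop("empty header cell in ", path)
  body <- tab[-1L, , drop = FALSE]
  sets <- lapply(seq_len(ncol(tab)), function(j) {
    col <- trimws(as.character(body[[j]]))
    col[nzchar(col)]
  })
  names(sets) <- header
  empty <- header[vapply(sets, length, 1L) == 0L]
  if (length(empty)) {
    message("empty set column(s): ", paste(empty, collapse = ", "))
  }
  set_collection(sets, background = background)
}

#' Write a collection to a GMT file
#'
#' @param x A [set_collection()].
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions
#'   (second GMT field); defaults to `"na"`.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(x, path, descriptions = NULL) {
  stopifnot(inherits(x, "set_collection"))
  if (is.null(descriptions)) descriptions <- rep("na", length(x$sets))
  lines <- mapply(function(nm, desc, members) {
    paste(c(nm, desc, members), collapse = "\t")
  }, names(x$sets), descriptions, x$sets)
  writeLines(lines, path)
  invisible(path)
}

#' Observed intersection of a combination of sets
#'
#' Counts the elements common to every named set (total, non-exclusive
#' overlap: members may also belong to sets outside the combination — this is
#' the quantity the exact test models).
#'
#' @param collection A [set_collection()].
#' @param combination Non-empty character vector of set names.
#' @return Integer intersection size.
#' @export
count_overlap <- function(collection, combination) {
  stopifnot(inherits(collection, "set_collection"))
  if (!length(combination)) stop("'combination' must name at least one set")
  missing <- setdiff(combination, names(collection$sets))
  if (length(missing)) stop("unknown set name(s): ", paste(missing, collapse = ", "))
  length(Reduce(intersect, collection$sets[combination]))
}

#' Exclusive (Venn-region) membership counts
#'
#' Partitions the union of all sets into disjoint regions by exact membership
#' pattern.  Each region is keyed by a length-`t` barcode over `{0,1}` (digit
#' `i` = membership in the `i`-th set); counts sum to the union size.  These
#' exclusive counts are display-oriented — the exact test is defined on total
#' overlaps, see [count_overlap()].
#'
#' @param collection A [set_collection()] with at most 20 sets.
#' @return Named integer vector of counts for the populated barcodes.
#' @export
exclusive_region_counts <- function(collection) {
  stopifnot(inherits(collection, "set_collection"))
  t <- length(collection$sets)
  if (t > 20L) stop("exclusive regions are limited to 20 sets (2^t patterns)")
  u <- unique(unlist(collection$sets, use.names = FALSE))
  if (!length(u)) return(integer(0))
  member <- vapply(collection$sets, function(s) u %in% s, logical(length(u)))
  member <- matrix(member, nrow = length(u))
  barcodes <- apply(member, 1L, function(b) paste(as.integer(b), collapse = ""))
  tab <- table(barcodes)
  structure(as.integer(tab), names = names(tab))
}
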