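#' Read a GMT gene set collection
#'
#' Parses the tab-separated GMT format used by MSigDB: one gene set per line,
#' fields `name<TAB>description<TAB>member1<TAB>member2...`. Duplicate member
#' tokens within a line are collapsed and empty tokens dropped; member order
#' is not meaningful.
#'
#' @param path Path to a GMT file (UTF-8).
#' @return A tibble with one row per gene set and columns `set` (character),
#'   `description` (character), `members` (list of character vectors) and
#'   `size` (integer).
#' @examples
#' f <- tempfile(fileext = ".gmt")
#' writeLines(c("S1\tfirst\tA\tB\tC", "S2\tsecond\tA\tA\tB"), f)
#' read_gmt(f)
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("GMT file not found: ", path))
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad) > 0L) {
    abort(paste0(
      "malformed GMT line ", bad[1L], " in '", path,
      "': expected at least 3 tab-separated fields, found ", lengths(fields)[bad[1L]]
    ))
  }
  sets <- vapply(fields, `[[`, character(1L), 1L)
  dup <- anyDuplicated(sets)
  if (dup > 0L) {
    abort(paste0("duplicate gene set name in '", path, "': ", sets[dup]))
  }
  members <- lapply(fields, function(f) {
    mem <- f[-(1:2)]
    unique(mem[nzchar(mem)])
  })
  empty <- which(lengths(members) == 0L)
  if (length(empty) > 0L) {
    abort(paste0("gene set '", sets[empty[1L]], "' has no non-empty members"))
  }
  tibble(
    set = sets,
    description = vapply(fields, `[[`, character(1L), 2L),
    members = members,
    size = lengths(members)
  )
}

#' Write a gene set collection to GMT
#'
#' @param collection A tibble as returned by [read_gmt()]; only `set`,
#'   `description` and `members` are used (a missing `description` is written
#'   as `"na"`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(is.data.frame(collection), all(c("set", "members") %in% names(collection)))
  desc <- if ("description" %in% names(collection)) collection$description else rep("na", nrow(collection))
  lines <- mapply(
    function(s, d, m) paste(c(s, d, m), collapse = "\t"),
    collection$set, desc, collection$members
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Restrict gene sets to a universe and drop small sets
#'
#' Intersects each set's members with the universe gene list and removes sets
#' whose post-intersection size falls below `min_size`. All downstream walk
#' statistics use the post-intersection size as the gene set size K, so this
#' is the canonical preparation step before [mgsea()].
#'
#' @param collection Gene set tibble from [read_gmt()], or a named list of
#'   character vectors.
#' @param universe Character vector of universe gene identifiers (no
#'   duplicates, at least 2 genes).
#' @param min_size Minimum number of members inside the universe for a set to
#'   be retained (default 50, the conventional floor for enrichment runs).
#' @param ignore_case Match identifiers case-insensitively. Default `FALSE`:
#'   matching is exact, case-sensitive string equality.
#' @return A tibble in the same shape as [read_gmt()] output, with `members`
#'   intersected with the universe and `size` updated.
#' @export
restrict_gene_sets <- function(collection, universe, min_size = 50L, ignore_case = FALSE) {
  collection <- as_gene_sets(collection)
  if (length(universe) == 0L) abort("empty universe")
  if (anyDuplicated(universe) > 0L) abort("universe contains duplicate gene identifiers")
  if (length(universe) < 2L) abort("universe must contain at least 2 genes")
  if (min_size < 1L) abort("min_size must be >= 1")
  uni <- if (ignore_case) toupper(universe) else universe
  out <- collection
  out$members <- lapply(collection$members, function(m) {
    key <- if (ignore_case) toupper(m) else m
    m[key %in% uni]
  })
  out$size <- lengths(out$members)
  out[out$size >= min_size, , drop = FALSE]
}

# Coerce a named list of member vectors to the collection tibble shape.
as_gene_sets <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("set", "members") %in% names(x)))
    if (anyDuplicated(x$set) > 0L) abort("duplicate gene set names in collection")
    if (!"size" %in% names(x)) x$size <- lengths(x$members)
    return(as_tibble(x))
  }
  if (is.list(x) && !is.null(names(x))) {
    if (anyDuplicated(names(x)) > 0L) abort("duplicate gene set names in collection")
    members <- unname(lapply(x, function(m) unique(as.character(m))))
    return(tibble(
      set = names(x),
      description = rep("na", length(x)),
      members = members,
      size = lengths(members)
    ))
  }
  abort("gene sets must be a tibble with columns set/members or a named list")
}
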