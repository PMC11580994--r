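#' Parse NCBI-style taxonomy dump files
#'
#' Reads the pipe-delimited `names.dmp`/`nodes.dmp` dialect (fields separated
#' by `"\t|\t"`, lines terminated `"\t|"`) into a `taxonomy_table`. Names of
#' class `scientific name` become primary names; all other name classes
#' (synonym, equivalent name, ...) are kept as synonyms. The resulting name
#' index is case-insensitive after whitespace/underscore normalization, so
#' heterogeneous profiler spellings of one taxon resolve to one numeric ID.
#'
#' @param names a file path or a character vector of `names.dmp` lines.
#' @param nodes a file path or a character vector of `nodes.dmp` lines.
#' @return an object of class `taxonomy_table` with components `nodes`
#'   (data.frame: `taxon_id`, `parent_id`, `rank`, `scientific_name`),
#'   `synonyms` (data.frame: `taxon_id`, `name`) and `name_index`
#'   (data.frame: `key`, `taxon_id`).
#' @export
parse_taxonomy_dump <- function(names, nodes) {
  name_lines <- read_dump_lines(names)
  node_lines <- read_dump_lines(nodes)

  nf <- split_dump(node_lines, "nodes.dmp", min_fields = 3)
  node_df <- data.frame(
    taxon_id  = as_taxid(nf[, 1], node_lines, "nodes.dmp"),
    parent_id = as_taxid(nf[, 2], node_lines, "nodes.dmp"),
    rank      = nf[, 3],
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(node_df$taxon_id))
    stop_mdm("duplicate taxon_id in nodes.dmp", class = "mdmbench_parse_error")

  mf <- split_dump(name_lines, "names.dmp", min_fields = 4)
  name_df <- data.frame(
    taxon_id = as_taxid(mf[, 1], name_lines, "names.dmp"),
    name = mf[, 2],
    class = mf[, 4],
    stringsAsFactors = FALSE
  )

  orphan <- !(node_df$parent_id %in% node_df$taxon_id)
  if (any(orphan))
    stop_mdm("orphan parent_id in nodes.dmp: ",
             paste(unique(node_df$parent_id[orphan]), collapse = ", "),
             class = "mdmbench_structure_error")
  bad_name <- !(name_df$taxon_id %in% node_df$taxon_id)
  if (any(bad_name))
    stop_mdm("names.dmp refers to unknown taxon_id: ",
             paste(unique(name_df$taxon_id[bad_name]), collapse = ", "),
             class = "mdmbench_structure_error")

  sci <- name_df[name_df$class == "scientific name", , drop = FALSE]
  node_df$scientific_name <- sci$name[match(node_df$taxon_id, sci$taxon_id)]
  node_df$scientific_name[is.na(node_df$scientific_name)] <-
    paste0("taxid_", node_df$taxon_id[is.na(node_df$scientific_name)])
  syn <- name_df[name_df$class != "scientific name", c("taxon_id", "name")]
  rownames(node_df) <- rownames(syn) <- NULL

  new_taxonomy_table(node_df, syn)
}

new_taxonomy_table <- function(node_df, syn) {
  all_names <- data.frame(
    key = normalize_name(c(node_df$scientific_name, syn$name)),
    taxon_id = c(node_df$taxon_id, syn$taxon_id),
    stringsAsFactors = FALSE
  )
  all_names <- unique(all_names)
  # one string, several taxon_ids: keep the smallest id, deterministically
  all_names <- all_names[order(all_names$key, all_names$taxon_id), , drop = FALSE]
  dup <- duplicated(all_names$key)
  if (any(dup)) {
    warning("ambiguous taxon name(s) resolved to smallest taxon_id: ",
            paste(unique(all_names$key[dup]), collapse = ", "))
    all_names <- all_names[!dup, , drop = FALSE]
  }
  rownames(all_names) <- NULL
  structure(list(nodes = node_df, synonyms = syn, name_index = all_names),
            class = "taxonomy_table")
}

read_dump_lines <- function(x) {
  if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) readLines(x)
  else if (length(x) == 1 && grepl("\n", x)) strsplit(x, "\n", fixed = TRUE)[[1]]
  else as.character(x)
}

split_dump <- function(lines, what, min_fields) {
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    stop_mdm("empty ", what, class = "mdmbench_parse_error")
  ok_term <- grepl("\t\\|$", lines)
  if (any(!ok_term))
    stop_mdm("malformed ", what, " line ", which(!ok_term)[1],
             ": missing '\\t|' terminator", class = "mdmbench_parse_error")
  body <- sub("\t\\|$", "", lines)
  parts <- strsplit(body, "\t|\t", fixed = TRUE)
  n <- lengths(parts)
  if (any(n < min_fields))
    stop_mdm("malformed ", what, " line ", which(n < min_fields)[1],
             ": expected >= ", min_fields, " fields", class = "mdmbench_parse_error")
  t(vapply(parts, function(p) p[seq_len(min_fields)], character(min_fields)))
}

as_taxid <- function(x, lines, what) {
  id <- suppressWarnings(as.integer(x))
  if (anyNA(id) || any(id <= 0))
    stop_mdm("malformed ", what, " line ",
             which(is.na(id) | id <= 0)[1], ": bad taxon_id",
             class = "mdmbench_parse_error")
  id
}

#' @export
print.taxonomy_table <- function(x, ...) {
  cat("taxonomy_table:", nrow(x$nodes), "nodes,",
      nrow(x$synonyms), "synonyms,",
      nrow(x$name_index), "indexed names\n")
  rk <- table(x$nodes$rank)
  cat("  ranks:", paste(names(rk), rk, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Write a taxonomy table back to dump dialect
#'
#' Inverse of [parse_taxonomy_dump()]: re-parsing the emitted lines yields an
#' identical table.
#'
#' @param taxonomy a `taxonomy_table`.
#' @param names_path,nodes_path optional output file paths.
#' @return invisibly, a list with character vectors `names` and `nodes`.
#' @export
write_taxonomy_dump <- function(taxonomy, names_path = NULL, nodes_path = NULL) {
  nd <- taxonomy$nodes
  nodes <- paste0(nd$taxon_id, "\t|\t", nd$parent_id, "\t|\t", nd$rank, "\t|")
  nm <- c(
    paste0(nd$taxon_id, "\t|\t", nd$scientific_name,
           "\t|\t\t|\tscientific name\t|"),
    if (nrow(taxonomy$synonyms))
      paste0(taxonomy$synonyms$taxon_id, "\t|\t", taxonomy$synonyms$name,
             "\t|\t\t|\tsynonym\t|")
  )
  if (!is.null(names_path)) writeLines(nm, names_path)
  if (!is.null(nodes_path)) writeLines(nodes, nodes_path)
  invisible(list(names = nm, nodes = nodes))
}

#' Map raw database taxon names to numeric taxonomy IDs
#'
#' Each name resolves through the normalized name index (scientific names and
#' synonyms alike); names absent from the taxonomy are recorded as
#' unmappable (`NA`). Misses are data, not errors: real profiler databases
#' always contain taxa the reference taxonomy lacks.
#'
#' @param database_taxa character vector of taxon names as a profiler's
#'   database reports them.
#' @param taxonomy a `taxonomy_table`.
#' @return a `name_map`: data.frame with columns `name` and `taxon_id`
#'   (integer, `NA` = unmappable), one row per unique input name.
#' @export
build_name_map <- function(database_taxa, taxonomy) {
  stopifnot(inherits(taxonomy, "taxonomy_table"))
  nm <- unique(as.character(database_taxa))
  idx <- taxonomy$name_index
  out <- data.frame(
    name = nm,
    taxon_id = idx$taxon_id[match(normalize_name(nm), idx$key)],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$name), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("name_map", "data.frame")
  out
}

#' @export
print.name_map <- function(x, ...) {
  cat("name_map:", nrow(x), "names,",
      sum(!is.na(x$taxon_id)), "mapped,",
      sum(is.na(x$taxon_id)), "unmappable\n")
  invisible(x)
}

#' Read/write a name map as two-column TSV
#'
#' Unmappable names are stored with the literal string `NA`.
#' @param x a `name_map`.
#' @param path file path.
#' @return `read_name_map` returns a `name_map`.
#' @export
write_name_map <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_name_map
#' @export
read_name_map <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, quote = "",
                   colClasses = c("character", "integer"))
  class(df) <- c("name_map", "data.frame")
  df
}

#' Harmonize a name-keyed profile to taxonomy IDs
#'
#' Converts raw method-reported taxon names into standardized numeric IDs via
#' a [build_name_map()] result. Abundances are preserved (no renormalization);
#' names mapping to the same ID are summed; mass on unmappable names is
#' returned separately so callers can decide how to treat it.
#'
#' @param raw named numeric vector of nonnegative abundances, or an
#'   `assigned_profile` keyed by name.
#' @param name_map a `name_map` covering (at least) the profile's names.
#' @return a list with `entries` (numeric vector named by taxon_id),
#'   `unmappable_mass`, and `unknown_mass` (carried through unchanged for an
#'   `assigned_profile` input).
#' @export
harmonize_profile <- function(raw, name_map) {
  unknown_mass <- 0
  rank <- NA_character_
  if (inherits(raw, "assigned_profile")) {
    unknown_mass <- raw$unknown_mass
    rank <- raw$rank
    raw <- raw$entries
  }
  if (any(raw < 0))
    stop_mdm("negative abundance in profile", class = "mdmbench_validation_error")
  ids <- name_map$taxon_id[match(normalize_name(names(raw)),
                                 normalize_name(name_map$name))]
  mappable <- !is.na(ids)
  unmappable_mass <- sum(raw[!mappable])
  entries <- if (any(mappable)) {
    v <- tapply(raw[mappable], ids[mappable], sum)
    setNames(as.numeric(v), names(v))
  } else numeric(0)
  list(entries = entries, unmappable_mass = unmappable_mass,
       unknown_mass = unknown_mass, rank = rank)
}

#' Find the ancestor of a taxon at a requested rank
#'
#' Walks the parent chain (traversing non-canonical ranks transparently) and
#' returns the ancestor whose rank matches, or `NA` if the chain lacks that
#' rank — e.g. querying a phylum node at species rank.
#'
#' @param taxon_id integer taxon id present in the table.
#' @param rank a canonical rank name.
#' @param taxonomy a `taxonomy_table`.
#' @return integer taxon id or `NA`.
#' @export
lineage_query <- function(taxon_id, rank, taxonomy) {
  rank <- match.arg(rank, CANONICAL_RANKS)
  nd <- taxonomy$nodes
  i <- match(taxon_id, nd$taxon_id)
  if (is.na(i))
    stop_mdm("taxon_id ", taxon_id, " not in taxonomy",
             class = "mdmbench_lookup_error")
  repeat {
    if (identical(nd$rank[i], rank)) return(nd$taxon_id[i])
    parent <- nd$parent_id[i]
    if (parent == nd$taxon_id[i]) return(NA_integer_)  # reached root
    i <- match(parent, nd$taxon_id)
  }
}

#' Full canonical lineage of a taxon
#'
#' @inheritParams lineage_query
#' @return named integer vector over the canonical ranks (`NA` where the
#'   parent chain lacks a rank).
#' @export
full_lineage <- function(taxon_id, taxonomy) {
  nd <- taxonomy$nodes
  i <- match(taxon_id, nd$taxon_id)
  if (is.na(i))
    stop_mdm("taxon_id ", taxon_id, " not in taxonomy",
             class = "mdmbench_lookup_error")
  out <- setNames(rep(NA_integer_, length(CANONICAL_RANKS)), CANONICAL_RANKS)
  repeat {
    r <- nd$rank[i]
    if (r %in% CANONICAL_RANKS && is.na(out[r])) out[r] <- nd$taxon_id[i]
    parent <- nd$parent_id[i]
    if (parent == nd$taxon_id[i]) break
    i <- match(parent, nd$taxon_id)
  }
  out
}
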