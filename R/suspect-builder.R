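# Assembly of the site-relevant suspect list from the monitored-target
# registry and the key-metabolite (PPDB-style) table.

#' Assemble the suspect list
#'
#' The list comprises (i) all monitored target compounds, (ii) all key
#' metabolites of those targets, (iii) additional parent compounds of
#' monitoring interest (newly registered, seed treatments, parents of
#' already-monitored TPs, special concern), and (iv) all key metabolites of
#' those additional parents. Every entry is annotated with its neutral
#' monoisotopic mass and expected m/z in both ionization polarities. A
#' metabolite listed under several parents is collapsed to a single entry
#' with merged parent ids (disable with `collapse_shared = FALSE`).
#'
#' @param registry Data frame of registry entries: `compound_id`, `name`,
#'   `formula`, `role` ("monitored_target" or "additional_parent"),
#'   `addition_category` (NA unless additional parent), `registered_sites`
#'   (";"-separated site ids).
#' @param metabolites Data frame of key-metabolite records: `parent_id`,
#'   `tp_id`, `tp_name`, `formula`, `k_foc`, `parent_k_foc` (K_foc in mL/g,
#'   NA when unavailable).
#' @param collapse_shared Collapse metabolites shared between parents into a
#'   single entry keyed by canonical formula + normalized name.
#' @return Data frame of suspect entries: `suspect_id`, `name`, `formula`,
#'   `neutral_mass`, `mz_pos`, `mz_neg`, `origin` ("target", "key_metabolite"
#'   or "added_parent"), `parent_ids` (";"-joined, empty unless metabolite),
#'   `k_foc`.
#' @export
build_suspect_list <- function(registry, metabolites, collapse_shared = TRUE) {
  .check_cols(registry, c("compound_id", "name", "formula", "role"),
              "registry")
  if (nrow(metabolites))
    .check_cols(metabolites, c("parent_id", "tp_id", "tp_name", "formula"),
                "metabolites")
  if (nrow(registry)) {
    bad_role <- !registry$role %in% c("monitored_target", "additional_parent")
    if (any(bad_role))
      stop("unknown role for registry entry ",
           registry$compound_id[which(bad_role)[1]])
  }
  if (nrow(metabolites)) {
    unresolved <- !metabolites$parent_id %in% registry$compound_id
    if (any(unresolved))
      stop("metabolite record ", metabolites$tp_id[which(unresolved)[1]],
           " has unresolvable parent_id ",
           sQuote(metabolites$parent_id[which(unresolved)[1]]))
  }

  entry <- function(id, name, formula, origin, parents, k_foc) {
    canon <- format_formula(parse_formula(formula))
    data.frame(
      suspect_id = id, name = name, formula = canon,
      neutral_mass = monoisotopic_mass(canon),
      mz_pos = ion_mz(canon, adduct = "[M+H]+"),
      mz_neg = ion_mz(canon, adduct = "[M-H]-"),
      origin = origin, parent_ids = parents,
      k_foc = if (is.null(k_foc) || is.na(k_foc)) NA_real_ else k_foc,
      stringsAsFactors = FALSE
    )
  }

  rows <- list()
  for (i in seq_len(nrow(registry))) {
    r <- registry[i, ]
    origin <- if (r$role == "monitored_target") "target" else "added_parent"
    rows[[length(rows) + 1L]] <-
      entry(r$compound_id, r$name, r$formula, origin, "", NA_real_)
  }
  for (i in seq_len(nrow(metabolites))) {
    m <- metabolites[i, ]
    rows[[length(rows) + 1L]] <-
      entry(m$tp_id, m$tp_name, m$formula, "key_metabolite", m$parent_id,
            if ("k_foc" %in% names(metabolites)) m$k_foc else NA_real_)
  }
  if (!length(rows)) {
    return(data.frame(suspect_id = character(0), name = character(0),
                      formula = character(0), neutral_mass = numeric(0),
                      mz_pos = numeric(0), mz_neg = numeric(0),
                      origin = character(0), parent_ids = character(0),
                      k_foc = numeric(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)

  if (collapse_shared) {
    key <- ifelse(
      out$origin == "key_metabolite",
      paste0(out$formula, "|", tolower(gsub("[^a-zA-Z0-9]", "", out$name))),
      paste0("id|", out$suspect_id)
    )
    keep <- !duplicated(key)
    merged <- vapply(split(out$parent_ids, key), function(p) {
      p <- unique(unlist(strsplit(p[nzchar(p)], ";", fixed = TRUE)))
      paste(sort(p), collapse = ";")
    }, character(1))
    out <- out[keep, , drop = FALSE]
    out$parent_ids <- unname(merged[key[keep]])
  }
  rownames(out) <- NULL
  out
}

#' Non-target subset of a suspect list
#'
#' Drops the monitored target compounds, leaving the entries actually screened
#' as suspects (key metabolites plus added parents).
#'
#' @param suspects Output of [build_suspect_list()].
#' @param tp_only Keep only transformation products (origin
#'   "key_metabolite"), excluding the added parents as well.
#' @return Subset of `suspects`.
#' @export
non_target_subset <- function(suspects, tp_only = FALSE) {
  keep <- if (tp_only) suspects$origin == "key_metabolite"
          else suspects$origin != "target"
  out <- suspects[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.check_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(what, " is missing column(s): ", paste(missing, collapse = ", "))
  invisible(df)
}

#' Write / read a suspect list as CSV
#'
#' Columns follow suspect-exchange conventions: name, formula, neutral
#' monoisotopic mass, both-polarity expected m/z, parent link(s), origin
#' category and K_foc. The reader re-validates masses against the stored
#' formula on load.
#'
#' @param suspects Suspect-list data frame.
#' @param path File path.
#' @return `read_suspect_list` returns the validated data frame.
#' @export
write_suspect_list <- function(suspects, path) {
  utils::write.csv(suspects, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_suspect_list
#' @export
read_suspect_list <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(parent_ids = "character"))
  .check_cols(df, c("suspect_id", "name", "formula", "neutral_mass",
                    "mz_pos", "mz_neg", "origin", "parent_ids", "k_foc"),
              "suspect list")
  df$parent_ids[is.na(df$parent_ids)] <- ""
  theo <- vapply(df$formula, monoisotopic_mass, numeric(1))
  if (any(abs(theo - df$neutral_mass) > 1e-4))
    stop("suspect list masses inconsistent with formulas at row ",
         which(abs(theo - df$neutral_mass) > 1e-4)[1])
  df
}
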