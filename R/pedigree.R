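# Pedigree container: parent-offspring trios with birth years. Unknown
# parents are coded NA internally; "0" and "" are accepted on input.

#' Construct and validate a pedigree
#'
#' @param records data frame with columns `id`, `sire`, `dam` and optionally
#'   `birth_year`. Unknown parents may be coded `NA`, `"0"` or `""`.
#' @param complete if `TRUE`, parents that have no record of their own are
#'   added as founders (with unknown birth year) instead of raising an error.
#' @return a `pedigree` data frame, topologically sorted so every parent
#'   precedes its offspring.
#' @details Validation rejects duplicated ids, self-parentage, ancestry
#'   cycles (the offending ids are named), and known parent birth years not
#'   preceding the offspring's.
#' @export
pedigree <- function(records, complete = FALSE) {
  df <- as.data.frame(records, stringsAsFactors = FALSE)
  assert(all(c("id", "sire", "dam") %in% names(df)),
         "pedigree needs columns id, sire, dam")
  if (!"birth_year" %in% names(df)) df$birth_year <- NA_integer_
  df <- df[c("id", "sire", "dam", "birth_year")]
  df$id <- as.character(df$id)
  norm <- function(x) { x <- as.character(x); x[x %in% c("0", "", "NA")] <- NA; x }
  df$sire <- norm(df$sire); df$dam <- norm(df$dam)
  df$birth_year <- suppressWarnings(as.integer(df$birth_year))
  assert(!anyDuplicated(df$id), "duplicated pedigree ids: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  self <- df$id == df$sire | df$id == df$dam
  assert(!any(self, na.rm = TRUE), "self-parentage for: ",
         paste(df$id[which(self)], collapse = ", "))

  parents <- setdiff(stats::na.omit(c(df$sire, df$dam)), df$id)
  if (length(parents)) {
    if (!complete)
      stop_bg("parents without pedigree records: ", paste(parents, collapse = ", "),
              "; use complete = TRUE to add them as founders")
    df <- rbind(data.frame(id = parents, sire = NA_character_, dam = NA_character_,
                           birth_year = NA_integer_, stringsAsFactors = FALSE), df)
  }

  df <- ped_topo_sort(df)

  sy <- df$birth_year[match(df$sire, df$id)]
  dy <- df$birth_year[match(df$dam, df$id)]
  bad <- (!is.na(sy) & !is.na(df$birth_year) & sy >= df$birth_year) |
         (!is.na(dy) & !is.na(df$birth_year) & dy >= df$birth_year)
  if (any(bad))
    warning("parent birth year does not precede offspring for: ",
            paste(utils::head(df$id[bad], 5), collapse = ", "),
            if (sum(bad) > 5) " ..." else "")
  rownames(df) <- NULL
  class(df) <- c("pedigree", "data.frame")
  df
}

# Kahn topological sort; errors naming a cycle if one exists.
ped_topo_sort <- function(df) {
  n <- nrow(df)
  idx <- seq_len(n)
  si <- match(df$sire, df$id); di <- match(df$dam, df$id)
  indeg <- (!is.na(si)) + (!is.na(di))
  children <- vector("list", n)
  for (i in idx) {
    for (p in c(si[i], di[i])) if (!is.na(p))
      children[[p]] <- c(children[[p]], i)
  }
  order <- integer(0)
  queue <- which(indeg == 0)
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    order <- c(order, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) < n)
    stop_bg("pedigree contains an ancestry cycle involving: ",
            paste(df$id[setdiff(idx, order)], collapse = ", "),
            class = "breedgain_cycle_error")
  df[order, , drop = FALSE]
}

#' @export
print.pedigree <- function(x, ...) {
  founders <- sum(is.na(x$sire) & is.na(x$dam))
  cat(sprintf("pedigree: %d individuals (%d founders)", nrow(x), founders))
  if (any(!is.na(x$birth_year)))
    cat(sprintf(", birth years %d-%d", min(x$birth_year, na.rm = TRUE),
                max(x$birth_year, na.rm = TRUE)))
  cat("\n")
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}
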