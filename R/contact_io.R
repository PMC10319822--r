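#' Read species-contact data from file
#'
#' Two dialects are supported. The long dialect is a TSV with columns
#' `species_a`, `species_b`, `wins_a`, `wins_b`, `draws`: one row per
#' unordered species pair (`wins_a` = wins of `species_a` over `species_b`),
#' plus optional diagonal rows with `species_a == species_b` where `wins_a`
#' counts intraspecific overgrowth events and `draws` intraspecific ties.
#' The wide dialect supplies the S x S win-count and draw-count matrices as
#' headed CSV files. Abundances always come from a separate TSV with columns
#' `species`, `colonies`. The dialect is auto-detected from the header of
#' `contacts_path` unless `format` is given.
#'
#' Species absent from the contests file but present in the abundance file
#' get all-zero count rows. A draw recorded in only one direction of a pair
#' is filled in by symmetry; conflicting non-zero draw counts are an error.
#'
#' @param contacts_path path to the contests file (long TSV or wide win CSV).
#' @param abundance_path path to the abundance TSV.
#' @param draws_path path to the draw-count CSV (wide dialect only).
#' @param format `"auto"`, `"long"` or `"wide"`.
#' @param assemblage_id label; defaults to the contests file name.
#' @return A validated [contact_data] object; species order follows the
#'   abundance file.
#' @export
read_contacts <- function(contacts_path, abundance_path, draws_path = NULL,
                          format = c("auto", "long", "wide"),
                          assemblage_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(contacts_path)) stop("file not found: ", contacts_path)
  if (!file.exists(abundance_path)) stop("file not found: ", abundance_path)
  ab <- utils::read.delim(abundance_path, stringsAsFactors = FALSE)
  if (!all(c("species", "colonies") %in% names(ab))) {
    stop("abundance file must have columns 'species' and 'colonies'")
  }
  species <- as.character(ab$species)
  assemblage_id <- assemblage_id %||%
    sub("\\.[^.]+$", "", basename(contacts_path))

  if (format == "auto") {
    header <- strsplit(readLines(contacts_path, n = 1), "[\t,]")[[1]]
    format <- if ("species_a" %in% header) "long" else "wide"
  }
  S <- length(species)
  wins <- matrix(0, S, S, dimnames = list(species, species))
  draws <- matrix(0, S, S, dimnames = list(species, species))

  if (format == "long") {
    tab <- utils::read.delim(contacts_path, stringsAsFactors = FALSE)
    need <- c("species_a", "species_b", "wins_a", "wins_b", "draws")
    if (!all(need %in% names(tab))) {
      stop("parse error: long contests file must have columns ",
           paste(need, collapse = ", "))
    }
    for (r in seq_len(nrow(tab))) {
      a <- as.character(tab$species_a[r]); b <- as.character(tab$species_b[r])
      if (!a %in% species || !b %in% species) {
        stop(sprintf("parse error at line %d: unknown species '%s'",
                     r + 1, if (a %in% species) b else a))
      }
      vals <- c(tab$wins_a[r], tab$wins_b[r], tab$draws[r])
      if (any(is.na(vals))) {
        stop(sprintf("parse error at line %d: missing count", r + 1))
      }
      if (a == b) {
        wins[a, a] <- wins[a, a] + tab$wins_a[r]
        draws[a, a] <- draws[a, a] + tab$draws[r]
      } else {
        wins[a, b] <- wins[a, b] + tab$wins_a[r]
        wins[b, a] <- wins[b, a] + tab$wins_b[r]
        dr <- tab$draws[r]
        # symmetrise: one record covers the unordered pair, so a reverse row
        # restating the same draw count is not double-counted
        if (dr != 0) {
          if (draws[a, b] != 0 && draws[a, b] != dr) {
            stop(sprintf(
              "validation error: conflicting draw counts for pair (%s, %s)",
              a, b))
          }
          draws[a, b] <- dr
          draws[b, a] <- dr
        }
      }
    }
  } else {
    if (is.null(draws_path)) {
      stop("wide dialect needs 'draws_path' (draw-count CSV)")
    }
    wm <- as.matrix(utils::read.csv(contacts_path, row.names = 1))
    dm <- as.matrix(utils::read.csv(draws_path, row.names = 1))
    if (!setequal(rownames(wm), species) || !setequal(rownames(dm), species)) {
      stop("parse error: wide matrices must cover exactly the abundance species")
    }
    wins <- wm[species, species]
    dm <- dm[species, species]
    # fill one-sided draw records by symmetry
    draws <- pmax(dm, t(dm))
    conflict <- dm != 0 & t(dm) != 0 & dm != t(dm)
    if (any(conflict[upper.tri(conflict)])) {
      bad <- which(conflict & upper.tri(conflict), arr.ind = TRUE)[1, ]
      stop(sprintf(
        "validation error: conflicting draw counts for pair (%s, %s)",
        species[bad[1]], species[bad[2]]))
    }
  }
  contact_data(species, wins, draws, ab$colonies,
               assemblage_id = assemblage_id)
}

#' Write species-contact data to file
#'
#' Writes the long-dialect contests TSV and the abundance TSV read back by
#' [read_contacts()]; the composition of the two is the identity on valid
#' [contact_data].
#'
#' @param contacts a [contact_data] object.
#' @param contacts_path,abundance_path output paths.
#' @return Invisibly, `contacts`.
#' @export
write_contacts <- function(contacts, contacts_path, abundance_path) {
  stopifnot(inherits(contacts, "contact_data"))
  sp <- contacts$species
  rows <- win_loss_summary(contacts)
  rows$total <- NULL
  intra <- intraspecific_summary(contacts)
  intra <- intra[intra$overgrowths + intra$ties > 0, , drop = FALSE]
  if (nrow(intra) > 0) {
    rows <- rbind(rows, data.frame(
      species_a = intra$species, species_b = intra$species,
      wins_a = intra$overgrowths, wins_b = 0, draws = intra$ties,
      stringsAsFactors = FALSE))
  }
  utils::write.table(rows, contacts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(species = sp, colonies = as.integer(contacts$abundance)),
    abundance_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(contacts)
}
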