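# Controlled vocabularies: genes, sexes, organ codes, organ groups.
# Organ labels follow the registry convention of grouping cancers by organ of
# origin (first three ICD-9 positions); free-text or ICD mapping is out of
# scope -- inputs must already use these labels.

.GENES <- c("MLH1", "MSH2", "MSH6", "PMS2")
.SEXES <- c("F", "M")
.VITAL <- c("alive", "dead")
.TIMINGS <- c("previous", "prevalent", "prospective")

.ORGANS <- c("colon", "rectum", "endometrium", "ovary", "stomach",
             "small_intestine", "bile_duct", "pancreas", "ureter_kidney",
             "urinary_bladder", "prostate", "brain", "breast", "skin",
             "other")

# Core Lynch-syndrome cancer sites.  Breast and skin are carried through the
# incidence machinery but flagged non-LS (skin reporting is inconsistent
# across centres and breast cancer is not considered part of the syndrome);
# osteosarcoma is too infrequent for rate estimation and is not in the
# vocabulary.
.LS_ORGANS <- c("colon", "rectum", "endometrium", "ovary", "stomach",
                "small_intestine", "bile_duct", "pancreas", "ureter_kidney",
                "urinary_bladder", "prostate", "brain")

.FEMALE_ONLY <- c("endometrium", "ovary")
.MALE_ONLY <- "prostate"

#' Controlled vocabularies
#'
#' `organ_codes()` returns the full organ vocabulary, `ls_organs()` the
#' twelve core Lynch-syndrome cancer sites, and `mmr_genes()` the four
#' mismatch repair genes.  Sex-restricted organs (endometrium and ovary for
#' females, prostate for males) never appear for the other sex.
#'
#' @return A character vector of canonical (lower-case) labels.
#' @export
#' @examples
#' organ_codes()
#' ls_organs()
organ_codes <- function() .ORGANS

#' @rdname organ_codes
#' @export
ls_organs <- function() .LS_ORGANS

#' @rdname organ_codes
#' @export
mmr_genes <- function() .GENES

# TRUE when `organ` can occur in a carrier of sex `sex` (vectorised).
organ_sex_ok <- function(organ, sex) {
  !((organ %in% .FEMALE_ONLY & sex == "M") |
      (organ %in% .MALE_ONLY & sex == "F"))
}

#' Define a group of organs analysed as a single cancer site
#'
#' Groups of organs (e.g. colorectum = colon + rectum) are analysed like a
#' single site: a carrier's risk time for the group stops at the first
#' prospective cancer in any member organ, and a previous or prevalent cancer
#' in any member makes the carrier ineligible for the group.
#'
#' @param name Label for the group.
#' @param members Character vector of organ codes (see [organ_codes()]);
#'   case-insensitive, must be distinct.
#' @return An object of class `organ_group`.
#' @export
#' @examples
#' organ_group("colorectum", c("colon", "rectum"))
organ_group <- function(name, members) {
  members <- canon_vocab(members, .ORGANS, "organ")
  if (length(members) == 0L) stop("an organ group needs at least one member")
  if (anyDuplicated(members)) stop("organ group members must be distinct")
  structure(list(name = as.character(name)[1L], members = members),
            class = "organ_group")
}

#' @export
print.organ_group <- function(x, ...) {
  cat("<organ_group> ", x$name, ": ",
      paste(x$members, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Accept an organ_group, a single organ code, or a character vector of codes.
as_organ_group <- function(x) {
  if (inherits(x, "organ_group")) return(x)
  if (is.character(x)) {
    return(organ_group(paste(x, collapse = "+"), x))
  }
  stop("expected an organ_group or a character vector of organ codes")
}

#' Standard organ groups
#'
#' The three groupings used throughout: colorectum (colon + rectum),
#' gynaecological (endometrium + ovary) and the full set of core
#' Lynch-syndrome cancer sites.
#'
#' @return A named list of [organ_group()] objects.
#' @export
organ_groups <- function() {
  list(
    colorectum = organ_group("colorectum", c("colon", "rectum")),
    gynaecological = organ_group("gynaecological", c("endometrium", "ovary")),
    ls_cancers = organ_group("ls_cancers", .LS_ORGANS)
  )
}

# Canonicalise labels against a vocabulary (case-insensitive).  Unknown
# labels are passed through unchanged so that validate_cohort() can report
# them with the offending carrier id.
canon_vocab <- function(x, vocab, what, upper = FALSE) {
  x <- trimws(as.character(x))
  x <- if (upper) toupper(x) else tolower(x)
  bad <- setdiff(unique(x), vocab)
  if (length(bad) && what %in% c("organ")) {
    # organ groups are constructed programmatically: fail fast
    stop("unknown ", what, " code(s): ", paste(bad, collapse = ", "))
  }
  x
}

# Rounding half away from zero, the convention used for displayed
# percentages (e.g. 1.59 -> 2, 0.999 -> 1, 0.459 -> 0).
#' Round half away from zero
#'
#' Display rounding used for reported percentages: exact halves round away
#' from zero (`2.5 -> 3`), unlike [round()]'s round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_away(c(1.59, 0.459, 2.5))
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
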