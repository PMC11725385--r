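# DIV profile names, registries and containment relations.

#' Parse a dash-delimited DIV profile name
#'
#' Profile names concatenate member variant names with `-`; variant
#' names may contain underscores (`C_1365`) but never dashes, so the
#' split is unambiguous.
#'
#' @param name a single nonempty profile name, e.g.
#'   `"C15-C15dq-C15dr-C_1365"`.
#' @return Ordered character vector of member variant names.
#' @examples
#' parseProfileName("C15-C15dq-C15dr-C_1365")
#' @export
parseProfileName <- function(name) {
  if (!is.character(name) || length(name) != 1L || is.na(name) ||
      !nzchar(name))
    .stopf("profile name must be a single nonempty string")
  members <- strsplit(name, "-", fixed = TRUE)[[1L]]
  if (length(members) == 0L || any(!nzchar(members)))
    .stopf("malformed profile name '%s': empty member token", name)
  members
}

#' Build a profile registry from profile names
#'
#' Parses each name into its member variants and records the profiles
#' together with the background and low-depth read thresholds.  Nesting
#' (member-set containment) between registered profiles is queryable via
#' [profileContains()] and [containmentMatrix()].
#'
#' @param profileNames character vector of unique, parseable profile
#'   names.
#' @param backgroundReadThreshold,lowDepthThreshold see
#'   [ProfileRegistry()].
#' @return A [ProfileRegistry-class].
#' @examples
#' reg <- buildRegistry(c("C15", "C15-C15dq", "C15-C15dq-C15dr"))
#' profileContains(reg, "C15-C15dq", "C15")
#' @export
buildRegistry <- function(profileNames, backgroundReadThreshold = 200,
                          lowDepthThreshold = 1000) {
  if (anyDuplicated(profileNames))
    .stopf("duplicate profile names: %s",
           paste(unique(profileNames[duplicated(profileNames)]),
                 collapse = ", "))
  profiles <- lapply(profileNames, function(nm) DIVProfile(parseProfileName(nm)))
  ProfileRegistry(profiles,
                  backgroundReadThreshold = backgroundReadThreshold,
                  lowDepthThreshold = lowDepthThreshold)
}

#' Does profile `a` contain profile `b`?
#'
#' Containment is member-set inclusion: `a` contains `b` when every
#' member of `b` is also a member of `a`.
#'
#' @param registry a [ProfileRegistry-class].
#' @param a,b registered profile names.
#' @export
profileContains <- function(registry, a, b) {
  all(profileMembers(registry, b) %in% profileMembers(registry, a))
}

#' Pairwise containment relations of a registry
#'
#' @param registry a [ProfileRegistry-class].
#' @return Logical matrix `M` with `M[a, b]` TRUE when profile `a`
#'   contains profile `b` (member-set inclusion).
#' @export
containmentMatrix <- function(registry) {
  nm <- profileNames(registry)
  members <- lapply(nm, function(x) profileMembers(registry, x))
  M <- matrix(FALSE, length(nm), length(nm), dimnames = list(nm, nm))
  for (i in seq_along(nm))
    for (j in seq_along(nm))
      M[i, j] <- all(members[[j]] %in% members[[i]])
  M
}

#' Generate the nested prefix family of a dominant profile
#'
#' Given the ordered members of a maximal DIV profile, registers every
#' prefix of the member list as a profile (the nested, overlapping
#' family structure: `C15`, `C15-C15dq`, `C15-C15dq-C15dr`,
#' `C15-C15dq-C15dr-C_1365`), plus a singleton profile for each
#' background variant.
#'
#' @param members ordered member variant names of the maximal profile.
#' @param proportions per-member proportions of the dominant fraction
#'   (same length as `members`, strictly positive, summing to 1 within
#'   1e-9).  Used only for validation of the configuration here; the
#'   registry itself stores membership, not abundance.
#' @param background optional character vector of background variant
#'   names to register as singleton profiles.
#' @param backgroundReadThreshold,lowDepthThreshold see
#'   [ProfileRegistry()].
#' @return A [ProfileRegistry-class] with `length(members)` nested
#'   profiles plus one singleton per background variant.
#' @examples
#' generateProfileLibrary(c("C15", "C15dq", "C15dr", "C_1365"),
#'                        c(0.70, 0.15, 0.10, 0.05))
#' @export
generateProfileLibrary <- function(members, proportions,
                                   background = character(0),
                                   backgroundReadThreshold = 200,
                                   lowDepthThreshold = 1000) {
  if (length(members) == 0L) .stopf("members must be nonempty")
  if (length(proportions) != length(members))
    .stopf("members and proportions must have the same length")
  if (any(!is.finite(proportions)) || any(proportions <= 0))
    .stopf("proportions must be strictly positive")
  if (abs(sum(proportions) - 1) > 1e-9)
    .stopf("proportions must sum to 1 (got %.12f)", sum(proportions))
  profiles <- lapply(seq_along(members),
                     function(i) DIVProfile(members[seq_len(i)]))
  profiles <- c(profiles, lapply(background, DIVProfile))
  ProfileRegistry(profiles,
                  backgroundReadThreshold = backgroundReadThreshold,
                  lowDepthThreshold = lowDepthThreshold)
}
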