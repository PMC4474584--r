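#' Small deterministic in-memory corpus for examples and tests
#'
#' Twelve hand-specified care episodes over three ICD-10 codes (J21.1,
#' J21.2, K55.0), four episodes per code, each concluded by a discharge
#' summary, with fixed literal token content (no randomness). Episodes
#' `fx03`/`fx04` carry the same two clinical notes in opposite temporal
#' order, so their optimal note pairing crosses: the assignment and
#' alignment similarity schemes provably diverge on this pair. One note of
#' `fx01` mentions its ICD-10 code in free text.
#'
#' @return A `care_corpus` of 12 episodes.
#' @export
generate_fixture_small <- function() {
  pools <- list(
    "J21.1" = c("bronkioliitti", "hengitysvaikeus", "rsv", "apnea",
                "saturaatio"),
    "J21.2" = c("bronkiitti", "yskos", "obstruktio", "inhalaatio",
                "spirometria"),
    "K55.0" = c("iskemia", "suolisto", "nekroosi", "laparotomia",
                "resektio"))
  fever <- c("kuume", "infektio", "crp", "antibiootti", "verikoe")
  shared <- c("potilas", "vointi", "osasto", "seuranta", "laake", "kotiutus")

  mknote <- function(eid, pos, sentences, summary = FALSE)
    clinical_note(sprintf("%s-n%02d", eid, pos + 1L), eid, pos,
                  sentences, is_summary = summary)
  rot <- function(x, k) x[((seq_along(x) + k - 1L) %% length(x)) + 1L]

  plain_episode <- function(eid, code, n_clinical, k) {
    pool <- pools[[code]]
    notes <- lapply(seq_len(n_clinical) - 1L, function(j) {
      s1 <- c(rot(pool, j + k)[1:3], shared[(j + k) %% 6 + 1])
      s2 <- c(shared[(j + 2 * k) %% 6 + 1], rot(pool, j + k + 2)[1:2])
      mknote(eid, j, list(s1, s2))
    })
    summ <- mknote(eid, n_clinical,
                   list(c(pool[1:3], "seuranta"), c(pool[4], "kotiutus")),
                   summary = TRUE)
    care_episode(eid, c(notes, list(summ)), code)
  }

  eps <- list(
    plain_episode("fx01", "J21.1", 4L, 0L),
    plain_episode("fx02", "J21.1", 5L, 1L),
    NULL, NULL,   # fx03 / fx04: crossing pair, built below
    plain_episode("fx05", "J21.2", 3L, 0L),
    plain_episode("fx06", "J21.2", 4L, 1L),
    plain_episode("fx07", "J21.2", 5L, 2L),
    plain_episode("fx08", "J21.2", 3L, 3L),
    plain_episode("fx09", "K55.0", 4L, 0L),
    plain_episode("fx10", "K55.0", 5L, 1L),
    plain_episode("fx11", "K55.0", 3L, 2L),
    plain_episode("fx12", "K55.0", 4L, 3L))

  x_sent <- list(c("bronkioliitti", "rsv", "hengitysvaikeus"),
                 c("saturaatio", "apnea", "potilas"))
  y_sent <- list(c("kuume", "infektio", "crp"),
                 c("antibiootti", "verikoe", "vointi"))
  cross_summary <- list(c("bronkioliitti", "kuume", "seuranta"),
                        c("rsv", "crp", "kotiutus"))
  eps[[3]] <- care_episode("fx03", list(
    mknote("fx03", 0L, x_sent), mknote("fx03", 1L, y_sent),
    mknote("fx03", 2L, cross_summary, summary = TRUE)), "J21.1")
  eps[[4]] <- care_episode("fx04", list(
    mknote("fx04", 0L, y_sent), mknote("fx04", 1L, x_sent),
    mknote("fx04", 2L, cross_summary, summary = TRUE)), "J21.1")

  # free-text code mention, exercised by query construction
  n2 <- eps[[1]]$notes[[2]]
  n2$sentences <- c(n2$sentences, list(c("dg", "j21.1")))
  eps[[1]]$notes[[2]] <- n2

  new_care_corpus(eps)
}
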