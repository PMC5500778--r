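# Closed filler vocabulary: French-like function/content words plus a few
# standalone punctuation marks (punctuation tokens count as words for the
# distance). Words that collide with a lexicon key are dropped at run time.
filler_vocabulary <- function() {
  c("je", "tu", "il", "elle", "on", "nous", "vous", "ils", "bonjour",
    "merci", "avec", "dans", "pour", "apres", "avant", "depuis", "hier",
    "soir", "matin", "semaine", "mois", "annee", "chose", "truc", "fois",
    "vraiment", "beaucoup", "peu", "trop", "aussi", "quand", "comme",
    "mais", "donc", "alors", "voila", "enfin", "puis", "encore", "jamais",
    "toujours", "peut", "etre", "avis", "forum", "message", "reponse",
    "question", "suite", "debut", "moment", "temps", "jour", "nuit",
    "famille", "travail", "maison", "chez", "moi", "toi", "lui", "ici",
    "bien", "mieux", "possible", "certain", "autre", "meme", "tout",
    "rien", "quelque", "plusieurs", ",", ".", "!", "?")
}

#' Simulation configuration for the synthetic forum corpus
#'
#' Defaults emulate the conditions of a mid-size French patient-forum
#' extraction: roughly 11.4% of planted (drug, disorder) pairs are true
#' adverse reactions; ADR distances are tightly concentrated around the drug
#' name (normal, mean 10, sd 30 words) while other co-occurrences follow a
#' wide two-component mixture (0.6 N(0, 80) + 0.4 N(0, 450)) producing the
#' long two-sided range seen in real posts; message lengths are log-normal
#' (meanlog 4.8, sdlog 1.0: median about 121 words with a heavy tail, about
#' 1.5% of messages beyond 1000 words); 41% of messages contain a drug but
#' no disorder.
#'
#' @param n_messages Number of messages to generate.
#' @param drugs Data.frame from [load_drug_list()] (or same columns).
#' @param lexicon Data.frame from [load_disorder_lexicon()].
#' @param adr_prevalence Probability a planted disorder is an ADR.
#' @param adr_distance_law `c(mean, sd)` of the normal law of ADR offsets.
#' @param other_distance_law Data.frame with columns `mean`, `sd`, `weight`
#'   (weights summing to 1) for non-ADR offsets.
#' @param message_length_law `c(meanlog, sdlog)` of the log-normal length law.
#' @param no_disorder_frac Fraction of messages with a drug but no disorder.
#' @param disorders_per_message Mean extra disorder count; each
#'   disorder-bearing message plants `1 + Poisson(disorders_per_message)`.
#' @param extra_drug_rate Probability of planting a second, more distant
#'   occurrence of the drug name (exercises min-distance deduplication).
#' @param misspelling_rate Per-token probability of perturbing a planted
#'   entity token.
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_messages = 648L,
                       drugs = NULL,
                       lexicon = NULL,
                       adr_prevalence = 0.114,
                       adr_distance_law = c(mean = 10, sd = 30),
                       other_distance_law = data.frame(
                         mean = c(0, 0), sd = c(80, 450), weight = c(0.6, 0.4)),
                       message_length_law = c(meanlog = 4.8, sdlog = 1.0),
                       no_disorder_frac = 0.41,
                       disorders_per_message = 3.3,
                       extra_drug_rate = 0.15,
                       misspelling_rate = 0.05,
                       seed = 1L) {
  if (is.null(drugs)) {
    drugs <- load_drug_list(system.file("extdata", "drugs_synthetic.csv",
                                        package = "adrdist", mustWork = TRUE))
  }
  if (is.null(lexicon)) {
    lexicon <- load_disorder_lexicon(system.file(
      "extdata", "disorder_lexicon_synthetic.csv",
      package = "adrdist", mustWork = TRUE))
  }
  stopifnot(adr_prevalence >= 0, adr_prevalence <= 1,
            adr_distance_law[["sd"]] > 0, all(other_distance_law$sd > 0),
            abs(sum(other_distance_law$weight) - 1) < 1e-9,
            misspelling_rate >= 0, misspelling_rate <= 1,
            no_disorder_frac >= 0, no_disorder_frac <= 1)
  structure(list(n_messages = as.integer(n_messages), drugs = drugs,
                 lexicon = lexicon, adr_prevalence = adr_prevalence,
                 adr_distance_law = adr_distance_law,
                 other_distance_law = other_distance_law,
                 message_length_law = message_length_law,
                 no_disorder_frac = no_disorder_frac,
                 disorders_per_message = disorders_per_message,
                 extra_drug_rate = extra_drug_rate,
                 misspelling_rate = misspelling_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Perturb a token like a forum misspelling
#'
#' With probability `rate` applies one of three perturbations chosen
#' uniformly: double a consonant, drop a vowel after the first vowel, or
#' swap two adjacent letters. The first two preserve the token's
#' [fuzzy_key()] by construction; the adjacent swap generally does not,
#' which documents the limit of fuzzy matching. Consumes the current RNG
#' stream (seed the session, not this function, for reproducibility).
#'
#' @param token Single token.
#' @param rate Probability of perturbation.
#' @param force One of `"double_consonant"`, `"drop_vowel"`, `"swap"` to
#'   force a specific perturbation (used in tests), or `NULL`.
#' @return The (possibly perturbed) token.
#' @export
plant_misspelling <- function(token, rate, force = NULL) {
  stopifnot(rate >= 0, rate <= 1)
  if (is.null(force)) {
    if (rate == 0 || stats::runif(1) >= rate) return(token)
    kind <- sample(c("double_consonant", "drop_vowel", "swap"), 1L)
  } else {
    kind <- match.arg(force, c("double_consonant", "drop_vowel", "swap"))
  }
  chars <- strsplit(token, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  if (n < 2L) return(token)
  vowel <- strsplit(fold_accents(token), "", fixed = TRUE)[[1L]] %in%
    c("a", "e", "i", "o", "u", "y")
  if (kind == "double_consonant") {
    cand <- which(!vowel)
    cand <- cand[cand > 1L]  # never double the initial letter
    if (!length(cand)) return(token)
    i <- if (length(cand) == 1L) cand else sample(cand, 1L)
    chars <- append(chars, chars[i], after = i)
  } else if (kind == "drop_vowel") {
    first_v <- which(vowel)[1L]
    cand <- which(vowel)
    cand <- cand[cand > first_v]
    if (!length(cand)) return(token)
    i <- if (length(cand) == 1L) cand else sample(cand, 1L)
    chars <- chars[-i]
  } else {
    i <- if (n == 2L) 1L else sample(seq_len(n - 1L), 1L)
    chars[c(i, i + 1L)] <- chars[c(i + 1L, i)]
  }
  paste(chars, collapse = "")
}

#' Generate a synthetic forum corpus with planted entities and gold labels
#'
#' Each message is a sequence of filler tokens into which one drug name
#' (sometimes a second, more distant occurrence of the same name) and zero
#' or more disorder terms are planted. Each planted disorder is an ADR with
#' probability `adr_prevalence`; its signed offset from the drug position is
#' drawn from the class-conditional law and realized exactly (the message is
#' extended when a drawn offset exceeds the drawn length, and the extension
#' is recorded). Offsets of zero are redrawn, as are offsets colliding with
#' already-placed entities. Any second drug occurrence is placed strictly
#' farther from every disorder than its planted offset, so the planted
#' occurrence is always the minimum-distance one.
#'
#' @param config A [sim_config()].
#' @return List with `messages` (data.frame: message_id, text, source, date),
#'   `gold` (message_id, llt_id, start_pos, label) and `truth` (one row per
#'   planted pair with the planted offset, drug/disorder positions and the
#'   `extended` flag).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  lex <- config$lexicon
  drugs <- config$drugs
  drug_idx <- build_index(drugs, mode = "fuzzy")
  dis_idx <- build_index(lex, mode = "exact-stemmed")
  fillers <- filler_vocabulary()
  fillers <- fillers[vapply(fillers, function(f) {
    nrow(index_lookup(dis_idx, dis_idx$keyfun(f))) == 0L &&
      nrow(index_lookup(drug_idx, drug_idx$keyfun(f))) == 0L
  }, logical(1))]
  lex_tokens <- lapply(strsplit(lex$surface_term, " ", fixed = TRUE),
                       function(t) t[t != ""])
  msgs <- vector("list", config$n_messages)
  gold <- list()
  truth <- list()
  for (i in seq_len(config$n_messages)) {
    id <- sprintf("msg%05d", i)
    L <- max(8L, as.integer(round(stats::rlnorm(
      1, config$message_length_law[["meanlog"]],
      config$message_length_law[["sdlog"]]))))
    drug_row <- drugs[sample(nrow(drugs), 1L), ]
    has_disorder <- stats::runif(1) >= config$no_disorder_frac
    n_dis <- if (has_disorder)
      min(1L + stats::rpois(1, config$disorders_per_message), 12L) else 0L
    # draw disorders: class, law offset, term
    plant <- list()
    if (n_dis > 0L) {
      for (j in seq_len(n_dis)) {
        is_adr <- stats::runif(1) < config$adr_prevalence
        off <- 0L
        for (try in 1:50) {
          off <- if (is_adr) {
            as.integer(round(stats::rnorm(1, config$adr_distance_law[["mean"]],
                                          config$adr_distance_law[["sd"]])))
          } else {
            comp <- sample(nrow(config$other_distance_law), 1L,
                           prob = config$other_distance_law$weight)
            as.integer(round(stats::rnorm(1, config$other_distance_law$mean[comp],
                                          config$other_distance_law$sd[comp])))
          }
          if (off != 0L && !off %in% vapply(plant, `[[`, integer(1), "off")) break
          off <- 0L
        }
        if (off == 0L) next
        term_i <- sample(nrow(lex), 1L)
        plant[[length(plant) + 1L]] <- list(off = off, term_i = term_i,
                                            is_adr = is_adr)
      }
    }
    offs <- vapply(plant, `[[`, integer(1), "off")
    spans <- vapply(plant, function(p) length(lex_tokens[[p$term_i]]), integer(1))
    drug_toks <- strsplit(drug_row$drug_name, " ", fixed = TRUE)[[1L]]
    # drug position: every planted offset must land at position >= 1
    min_off <- if (length(offs)) min(c(offs, 0L)) else 0L
    drug_pos <- 1L - min_off + sample(0:4, 1L)
    targets <- drug_pos + offs
    extended <- FALSE
    needed <- max(L, drug_pos + length(drug_toks) - 1L,
                  if (length(targets)) max(targets + spans - 1L) else 0L)
    if (needed > L) { L <- needed; extended <- TRUE }
    # resolve span collisions deterministically: drop later colliders
    occupied <- drug_pos:(drug_pos + length(drug_toks) - 1L)
    keep <- logical(length(plant))
    for (j in seq_along(plant)) {
      span <- targets[j]:(targets[j] + spans[j] - 1L)
      if (!any(span %in% occupied)) {
        keep[j] <- TRUE
        occupied <- c(occupied, span)
      }
    }
    plant <- plant[keep]; offs <- offs[keep]
    targets <- targets[keep]; spans <- spans[keep]
    # optional second occurrence of the same drug, strictly farther from
    # every disorder than its planted offset
    extra_pos <- NA_integer_
    if (stats::runif(1) < config$extra_drug_rate) {
      lower_bound <- max(c(occupied, targets + abs(offs)))
      extra_pos <- lower_bound + 2L + sample(0:3, 1L)
      extra_end <- extra_pos + length(drug_toks) - 1L
      if (extra_end > L) { L <- extra_end; extended <- TRUE }
      occupied <- c(occupied, extra_pos:extra_end)
    }
    tokens <- sample(fillers, L, replace = TRUE)
    place <- function(tokens, at, term_toks) {
      term_toks <- vapply(term_toks, plant_misspelling,
                          character(1), rate = config$misspelling_rate,
                          USE.NAMES = FALSE)
      tokens[at:(at + length(term_toks) - 1L)] <- term_toks
      tokens
    }
    tokens <- place(tokens, drug_pos, strsplit(drug_row$drug_name, " ",
                                               fixed = TRUE)[[1L]])
    if (!is.na(extra_pos)) {
      tokens <- place(tokens, extra_pos, strsplit(drug_row$drug_name, " ",
                                                  fixed = TRUE)[[1L]])
    }
    for (j in seq_along(plant)) {
      tokens <- place(tokens, targets[j], lex_tokens[[plant[[j]]$term_i]])
    }
    msgs[[i]] <- data.frame(
      message_id = id, text = paste(tokens, collapse = " "),
      source = "synthetic-forum", date = "2013-01-01",
      stringsAsFactors = FALSE)
    for (j in seq_along(plant)) {
      p <- plant[[j]]
      gold[[length(gold) + 1L]] <- data.frame(
        message_id = id, llt_id = lex$llt_id[p$term_i],
        start_pos = targets[j],
        label = if (p$is_adr) "ADR" else "OTHER", stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <- data.frame(
        message_id = id, llt_id = lex$llt_id[p$term_i],
        pt_id = lex$pt_id[p$term_i], drug_id = drug_row$drug_id,
        drug_pos = drug_pos, disorder_pos = targets[j], offset = p$off,
        label = if (p$is_adr) "ADR" else "OTHER",
        message_length = L, extended = extended, stringsAsFactors = FALSE)
    }
  }
  list(messages = if (length(msgs)) do.call(rbind, msgs) else
         data.frame(message_id = character(0), text = character(0),
                    source = character(0), date = character(0)),
       gold = if (length(gold)) do.call(rbind, gold) else
         data.frame(message_id = character(0), llt_id = character(0),
                    start_pos = integer(0), label = character(0)),
       truth = if (length(truth)) do.call(rbind, truth) else
         data.frame(message_id = character(0), llt_id = character(0),
                    pt_id = character(0), drug_id = character(0),
                    drug_pos = integer(0), disorder_pos = integer(0),
                    offset = integer(0), label = character(0),
                    message_length = integer(0), extended = logical(0)))
}
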