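#' Moment-matched discretized truncated normal
#'
#' Finds a normal location/scale whose discretization onto the integers
#' `lo..hi` (bins of width 1, renormalized) has the requested mean and SD,
#' and returns the resulting probability vector. Used to reproduce reported
#' count distributions that are summarized only by mean, SD and range.
#'
#' @param mean,sd Target moments of the discretized, truncated distribution.
#' @param lo,hi Integer support bounds.
#' @return Named numeric vector of probabilities over `lo:hi`.
#' @export
discrete_truncnorm <- function(mean, sd, lo, hi) {
  stopifnot(hi > lo, mean > lo, mean < hi, sd > 0)
  support <- lo:hi
  probs_for <- function(mu, sigma) {
    p <- stats::pnorm(support + 0.5, mu, sigma) -
      stats::pnorm(support - 0.5, mu, sigma)
    p / sum(p)
  }
  objective <- function(par) {
    p <- probs_for(par[1], exp(par[2]))
    m <- sum(support * p)
    s <- sqrt(sum((support - m)^2 * p))
    (m - mean)^2 + (s - sd)^2
  }
  fit <- stats::optim(c(mean, log(sd)), objective, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  stats::setNames(probs_for(fit$par[1], exp(fit$par[2])), support)
}

zipf_probs <- function(n, exponent) {
  p <- seq_len(n)^(-exponent)
  p / sum(p)
}

#' Conditional Poisson (maximum-entropy) sample of fixed size
#'
#' Draws a subset of exactly `k` distinct items with probability proportional
#' to the product of the selected items' weights. This is the
#' maximum-entropy design with those weights: conditional on the resulting
#' row and column totals, the incidence matrix it generates is uniform over
#' all matrices with the same margins -- precisely the null hypothesis of the
#' datastream permutation test. (A sequential weighted draw without
#' replacement does not have this property and injects margin-conditional
#' structure, which the permutation test correctly detects.)
#'
#' Uses the elementary-symmetric-polynomial recursion over suffixes for exact
#' sequential sampling in `O(length(w) * k)`.
#'
#' @param w Nonnegative item weights.
#' @param k Sample size (at most the number of positive weights).
#' @return Integer vector of `k` selected item indices.
#' @export
sample_cps <- function(w, k) {
  v <- length(w)
  stopifnot(k >= 0, all(w >= 0))
  if (k == 0) return(integer(0))
  n_pos <- sum(w > 0)
  if (k > n_pos) stop("sample_cps: k exceeds number of positive weights")
  w <- w / mean(w[w > 0])          # scale-invariant design; keeps ESPs in range
  # esp[i, l+1] = e_l(w_i, ..., w_v), backward recursion
  esp <- matrix(0, v + 1, k + 1)
  esp[v + 1, 1] <- 1
  for (i in v:1) {
    esp[i, 1] <- 1
    lmax <- min(k, v - i + 1)
    for (l in seq_len(lmax)) {
      esp[i, l + 1] <- esp[i + 1, l + 1] + w[i] * esp[i + 1, l]
    }
  }
  out <- integer(k)
  got <- 0L
  for (i in seq_len(v)) {
    r <- k - got
    if (r == 0L) break
    p_inc <- w[i] * esp[i + 1, r] / esp[i, r + 1]
    if (stats::runif(1) < p_inc) {
      got <- got + 1L
      out[got] <- i
    }
  }
  out[seq_len(got)]
}

#' Synthetic survey generator configuration
#'
#' Describes the population a synthetic survey is drawn from. The defaults
#' emulate the reference study's marginals: 286 participants; identity counts
#' per participant from a discretized truncated normal with mean 5.20, SD
#' 1.95 on 1--10; behaviour counts per identity (for identities with any
#' behaviours) with mean 2.06, SD 1.26 on 1--10; about one identity in five
#' listed with no behaviours; vocabularies of 138 identity and 83 behaviour
#' labels with Zipf-distributed popularity (exponents 1.0 and 1.6, which also
#' reproduce the study's filtered node counts under the more-than-three
#' filter).
#'
#' Identity sets are drawn by conditional Poisson (maximum-entropy) sampling
#' ([sample_cps()]), so that with no planted structure the generated
#' incidence matrix is, conditional on its margins, uniform over all matrices
#' with those margins -- the exact null of the datastream permutation test.
#'
#' Planted structure (all disabled by default) breaks that conditional
#' uniformity deliberately and is recorded as ground truth:
#'
#' * `blocks`: list of `list(identities = <labels or indices>, boost = b,
#'   rate = r)`. Each participant affiliates with at most one block
#'   (block `i` with probability `rate_i`, none otherwise); affiliation
#'   multiplies the sampling weight of the block's members by `b`, producing
#'   elevated within-block co-report.
#' * `dyads`: list of `list(pair = c(a, b), type = "preferred"|"avoided",
#'   effect = e)`. A preferred dyad is forced into a participant's identity
#'   set jointly with probability `e` (default 0.1), raising co-report beyond
#'   what the pair's margins explain. An avoided dyad is never allowed to
#'   co-occur.
#' * `behaviour_overlap` in `[0, 1]` mixes a shared behaviour pool
#'   (weight `overlap`) with an identity-specific shuffled pool, controlling
#'   how much behaviour profiles differ between identities.
#'
#' @param n_participants Number of participants.
#' @param identity_vocab,behaviour_vocab Vocabulary sizes.
#' @param identities_per_participant,behaviours_per_identity Lists
#'   `list(mean=, sd=, min=, max=)` for the two count distributions.
#' @param p_no_behaviours Probability an identity entry lists no behaviours.
#' @param identity_zipf,behaviour_zipf Popularity exponents.
#' @param behaviour_overlap Shared-pool mixing weight.
#' @param blocks,dyads Planted structure (see above).
#' @param seed Optional RNG seed used by [generate_survey()].
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_participants = 286,
                             identity_vocab = 138,
                             behaviour_vocab = 83,
                             identities_per_participant =
                               list(mean = 5.20, sd = 1.95, min = 1, max = 10),
                             behaviours_per_identity =
                               list(mean = 2.06, sd = 1.26, min = 1, max = 10),
                             p_no_behaviours = 0.19,
                             identity_zipf = 1.0,
                             behaviour_zipf = 1.6,
                             behaviour_overlap = 0.7,
                             blocks = list(),
                             dyads = list(),
                             seed = NULL) {
  stopifnot(n_participants >= 1, identity_vocab >= 2, behaviour_vocab >= 1,
            p_no_behaviours >= 0, p_no_behaviours <= 1,
            behaviour_overlap >= 0, behaviour_overlap <= 1)
  cfg <- list(n_participants = as.integer(n_participants),
              identity_vocab = as.integer(identity_vocab),
              behaviour_vocab = as.integer(behaviour_vocab),
              identities_per_participant = identities_per_participant,
              behaviours_per_identity = behaviours_per_identity,
              p_no_behaviours = p_no_behaviours,
              identity_zipf = identity_zipf,
              behaviour_zipf = behaviour_zipf,
              behaviour_overlap = behaviour_overlap,
              blocks = blocks,
              dyads = dyads,
              seed = seed)
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

identity_labels <- function(cfg) sprintf("id%03d", seq_len(cfg$identity_vocab))
behaviour_labels <- function(cfg) sprintf("bh%03d", seq_len(cfg$behaviour_vocab))

resolve_labels <- function(x, labels) {
  if (is.numeric(x)) {
    stopifnot(all(x >= 1), all(x <= length(labels)))
    labels[x]
  } else {
    stopifnot(all(x %in% labels))
    as.character(x)
  }
}

validate_generator_config <- function(cfg) {
  labels <- identity_labels(cfg)
  block_sets <- lapply(cfg$blocks, function(b) {
    stopifnot(is.numeric(b$boost), b$boost >= 1)
    if (!is.null(b$rate)) stopifnot(b$rate >= 0, b$rate <= 1)
    resolve_labels(b$identities, labels)
  })
  if (any(vapply(block_sets, length, 1L) > cfg$identity_vocab)) {
    stop("config error: planted block larger than the identity vocabulary")
  }
  rates <- vapply(cfg$blocks, function(b)
    if (is.null(b$rate)) 0.4 else b$rate, numeric(1))
  if (sum(rates) > 1) {
    stop("config error: block affiliation rates sum to more than 1")
  }
  for (d in cfg$dyads) {
    stopifnot(length(d$pair) == 2, d$type %in% c("preferred", "avoided"))
    pair <- resolve_labels(d$pair, labels)
    if (d$type == "avoided") {
      inside <- vapply(seq_along(block_sets), function(i) {
        all(pair %in% block_sets[[i]]) && cfg$blocks[[i]]$boost > 1
      }, logical(1))
      if (any(inside)) {
        stop("config error: avoided dyad planted inside a boosted block")
      }
    }
  }
  invisible(cfg)
}

#' Generate a synthetic survey dataset
#'
#' Draws a survey dataset from a [generator_config()]: each participant
#' samples an identity count, then identities sequentially without
#' replacement with probability proportional to Zipf popularity modified by
#' planted block and dyad structure; each (participant, identity) entry then
#' draws behaviours from that identity's profile (a mixture of a shared and
#' an identity-specific pool). The planted structure is recorded as ground
#' truth on the result.
#'
#' @param config A `generator_config`.
#' @return A `survey_data` object with attribute `ground_truth`: a list with
#'   the resolved planted `blocks` and `dyads` and the `config`. Retrieve it
#'   with [ground_truth()].
#' @export
generate_survey <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.null(config$seed)) set.seed(config$seed)

  v_i <- config$identity_vocab
  v_b <- config$behaviour_vocab
  ident_labels <- identity_labels(config)
  beh_labels <- behaviour_labels(config)

  ipp <- config$identities_per_participant
  bpi <- config$behaviours_per_identity
  ident_count_probs <- discrete_truncnorm(ipp$mean, ipp$sd, ipp$min,
                                          min(ipp$max, v_i))
  beh_count_probs <- discrete_truncnorm(bpi$mean, bpi$sd, bpi$min,
                                        min(bpi$max, v_b))

  pop_i <- zipf_probs(v_i, config$identity_zipf)
  pop_b <- zipf_probs(v_b, config$behaviour_zipf)

  blocks <- lapply(config$blocks, function(b) {
    list(members = match(resolve_labels(b$identities, ident_labels),
                         ident_labels),
         boost = b$boost,
         rate = if (is.null(b$rate)) 0.4 else b$rate)
  })
  dyads <- lapply(config$dyads, function(d) {
    list(pair = match(resolve_labels(d$pair, ident_labels), ident_labels),
         type = d$type,
         effect = if (is.null(d$effect)) {
           if (d$type == "preferred") 0.1 else 0
         } else {
           d$effect
         })
  })
  preferred <- Filter(function(d) d$type == "preferred", dyads)
  avoided <- Filter(function(d) d$type == "avoided", dyads)

  # identity-specific behaviour pools: a fixed shuffling of the shared
  # popularity ranks per identity, mixed with the shared pool
  specific_perm <- if (config$behaviour_overlap < 1) {
    t(vapply(seq_len(v_i), function(i) sample.int(v_b), integer(v_b)))
  } else {
    NULL
  }
  behaviour_probs <- function(i) {
    if (is.null(specific_perm)) return(pop_b)
    config$behaviour_overlap * pop_b +
      (1 - config$behaviour_overlap) * pop_b[specific_perm[i, ]]
  }

  supp_i <- as.integer(names(ident_count_probs))
  supp_b <- as.integer(names(beh_count_probs))

  out <- vector("list", config$n_participants)

  block_rates <- vapply(blocks, `[[`, numeric(1), "rate")

  for (p in seq_len(config$n_participants)) {
    pid <- sprintf("p%04d", p)
    k <- sample(supp_i, 1, prob = ident_count_probs)

    # latent block affiliation (at most one block per participant)
    w <- pop_i
    if (length(blocks) > 0) {
      u <- stats::runif(1)
      aff <- findInterval(u, cumsum(block_rates), left.open = TRUE) + 1L
      if (u < sum(block_rates)) {
        b <- blocks[[aff]]
        w[b$members] <- w[b$members] * b$boost
      }
    }

    # preferred dyads: forced joint inclusion with probability `effect`
    forced <- integer(0)
    for (d in preferred) {
      if (stats::runif(1) < d$effect) forced <- union(forced, d$pair)
    }
    k <- max(k, length(forced))

    w_rest <- w
    w_rest[forced] <- 0
    chosen <- NULL
    for (try in 1:100) {
      cand <- c(forced, sample_cps(w_rest, min(k - length(forced),
                                               sum(w_rest > 0))))
      bad <- FALSE
      for (d in avoided) {
        if (all(d$pair %in% cand)) { bad <- TRUE; break }
      }
      if (!bad) { chosen <- cand; break }
    }
    if (is.null(chosen)) {
      # give up on the size constraint: drop one member of an offending pair
      chosen <- cand
      for (d in avoided) {
        if (all(d$pair %in% chosen)) {
          chosen <- setdiff(chosen, sample(d$pair, 1))
        }
      }
    }
    plist <- vector("list", length(chosen))
    for (ci in seq_along(chosen)) {
      i <- chosen[ci]
      if (stats::runif(1) < config$p_no_behaviours) {
        plist[[ci]] <- data.frame(participant_id = pid,
                                  identity = ident_labels[i],
                                  behaviour = "")
      } else {
        nb <- min(sample(supp_b, 1, prob = beh_count_probs), v_b)
        bs <- sample_cps(behaviour_probs(i), nb)
        plist[[ci]] <- data.frame(participant_id = pid,
                                  identity = ident_labels[i],
                                  behaviour = beh_labels[bs])
      }
    }
    out[[p]] <- do.call(rbind, plist)
  }

  df <- do.call(rbind, out)
  survey <- as_survey(df)
  attr(survey, "ground_truth") <- list(
    blocks = lapply(blocks, function(b)
      list(identities = ident_labels[b$members], boost = b$boost)),
    dyads = lapply(dyads, function(d)
      list(pair = ident_labels[d$pair], type = d$type, effect = d$effect)),
    config = config
  )
  survey
}

#' Ground truth of a generated dataset
#'
#' @param x A `survey_data` produced by [generate_survey()].
#' @return The ground-truth list (planted blocks, dyads, config), or `NULL`
#'   for observed data.
#' @export
ground_truth <- function(x) attr(x, "ground_truth")

#' Generate a structureless (null) survey dataset
#'
#' As [generate_survey()] with all planted structure disabled: identities are
#' drawn independently given their popularity, and behaviours independently
#' from the shared marginal pool. Used for type-I-error calibration of the
#' permutation machinery.
#'
#' @param config A `generator_config`; its `blocks`/`dyads` are ignored and
#'   `behaviour_overlap` forced to 1.
#' @return A `survey_data` object.
#' @export
null_survey <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  config$blocks <- list()
  config$dyads <- list()
  config$behaviour_overlap <- 1
  generate_survey(config)
}
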