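#' Design configuration for a synthetic adoption cohort
#'
#' Defaults reproduce the study population structure: 74 children across 39
#' households, with 8 full-sibling pairs reared together, 6 full-sibling
#' pairs reared apart, 9 half-sibling pairs reared together, 122
#' half-sibling pairs reared apart and 31 nonbiological sibling pairs
#' reared together; ages 4.3-18.8 years, 49% male, sequencing depths
#' 39,523-73,295 reads.
#'
#' @param n_children cohort size.
#' @param n_homes number of households.
#' @param pairs named vector of pair-design counts (`full_together`,
#'   `full_apart`, `half_together`, `half_apart`, `unrelated_together`).
#' @param age_range min/max age in years (ages drawn log-uniformly).
#' @param sex_ratio probability of male (coded 1).
#' @param depth_range min/max sequencing depth (drawn uniformly).
#' @param max_sibship cap on constructed sibship size (useful for designs
#'   made of pairs only, e.g. parameter-recovery simulations).
#' @return list of class `design_config`.
#' @export
design_config <- function(n_children = 74, n_homes = 39,
                          pairs = c(full_together = 8, full_apart = 6,
                                    half_together = 9, half_apart = 122,
                                    unrelated_together = 31),
                          age_range = c(4.3, 18.8), sex_ratio = 0.49,
                          depth_range = c(39523, 73295),
                          max_sibship = Inf) {
  needed <- c("full_together", "full_apart", "half_together", "half_apart",
              "unrelated_together")
  missing <- setdiff(needed, names(pairs))
  if (length(missing)) stop("pairs missing: ", paste(missing, collapse = ", "))
  pairs <- as.integer(pairs[needed])
  names(pairs) <- needed
  if (any(pairs < 0)) stop("pair counts must be non-negative")
  structure(list(n_children = n_children, n_homes = n_homes, pairs = pairs,
                 age_range = age_range, sex_ratio = sex_ratio,
                 depth_range = depth_range, max_sibship = max_sibship),
            class = "design_config")
}

# Greedy decomposition of `p` pairs into clique sizes (>= 2, <= maxk).
decompose_pairs <- function(p, maxk = Inf, what = "pairs") {
  sizes <- integer(0)
  while (p > 0) {
    k <- min(floor((1 + sqrt(1 + 8 * p)) / 2), maxk)
    if (k < 2) stop("unrealizable design: cannot decompose ", p, " ", what,
                    " into sibships (size cap ", maxk, ")")
    sizes <- c(sizes, k)
    p <- p - choose(k, 2)
  }
  sizes
}

# Per sibship, how many members co-reside, so that the co-resident pair
# count over all sibships equals `together`.
allocate_coresidents <- function(sizes, together, what = "pairs") {
  j <- integer(length(sizes))
  rem <- together
  for (i in order(sizes, decreasing = TRUE)) {
    ji <- min(floor((1 + sqrt(1 + 8 * rem)) / 2), sizes[i])
    j[i] <- max(ji, 1L)
    rem <- rem - choose(j[i], 2)
  }
  if (rem != 0)
    stop("unrealizable design: cannot place ", together, " ", what,
         "-together pairs within sibships of sizes ",
         paste(sizes, collapse = "/"))
  j
}

# Fewest co-resident pairs obtainable by spreading `extras` surplus
# children over at most `m` homes (sizes as equal as possible).
min_pairs_spread <- function(extras, m) {
  if (extras == 0) return(0)
  if (m < 1) return(Inf)
  q <- extras %/% m
  r <- extras %% m
  (m - r) * choose(q + 1, 2) + r * choose(q + 2, 2)
}

# Sizes of the mixed (unrelated co-resident) homes: spend exactly `extras`
# surplus children over `ut` unordered co-resident pairs, using at most
# `max_homes` homes (the remaining children get single-occupancy homes).
allocate_mixed_homes <- function(ut, extras, max_homes = Inf) {
  feasible <- function(ut, ex, m) {
    if (ex == 0) return(ut == 0)
    m >= 1 && ut >= min_pairs_spread(ex, m) && ut <= choose(ex + 1, 2)
  }
  if (!feasible(ut, extras, max_homes))
    stop("unrealizable design: cannot realize ", ut,
         " unrelated-together pairs with ", extras,
         " children above one-per-home in ", max_homes, " homes")
  sizes <- integer(0)
  homes_left <- max_homes
  while (extras > 0) {
    kmax <- floor((1 + sqrt(1 + 8 * ut)) / 2)
    ok <- FALSE
    for (cand in rev(seq(2, max(kmax, 2)))) {
      if (cand - 1 > extras || choose(cand, 2) > ut) next
      if (feasible(ut - choose(cand, 2), extras - (cand - 1), homes_left - 1)) {
        k <- cand; ok <- TRUE; break
      }
    }
    if (!ok) stop("unrealizable design: mixed-home allocation failed with ",
                  ut, " pairs / ", extras, " extras left")
    sizes <- c(sizes, k)
    ut <- ut - choose(k, 2)
    extras <- extras - (k - 1)
    homes_left <- homes_left - 1
  }
  if (ut != 0) stop("unrealizable design: leftover unrelated-together pairs")
  sizes
}

#' Simulate the family/household design of an adoption cohort
#'
#' Constructs a pedigree and household assignment whose pair-type census
#' (full/half/unrelated x reared together/apart) matches the configuration
#' exactly; the census is recomputed from the result and verified before
#' returning. Ages are log-uniform over the configured range, sex is
#' Bernoulli, depths uniform, BMI Z-scores standard normal. The expected
#' relatedness matrix `K_true` holds 0.5 for full siblings (shared mother
#' and father), 0.25 for maternal half siblings and 0 otherwise.
#'
#' @param config a [design_config()].
#' @param seed integer seed.
#' @return list of class `synthetic_design`: `metadata`
#'   ([sample_metadata]), `K_true` ([pairwise_matrix] of kind
#'   `"relatedness"`), `pedigree` (data.frame child/mother/father), `config`.
#' @export
simulate_design <- function(config = design_config(), seed = 1) {
  stopifnot(inherits(config, "design_config"))
  p <- config$pairs
  full_sizes <- decompose_pairs(p["full_together"] + p["full_apart"],
                                config$max_sibship, "full-sib")
  half_sizes <- decompose_pairs(p["half_together"] + p["half_apart"],
                                config$max_sibship, "half-sib")
  full_j <- allocate_coresidents(full_sizes, p["full_together"], "full")
  half_j <- allocate_coresidents(half_sizes, p["half_together"], "half")
  n_sibs <- sum(full_sizes) + sum(half_sizes)
  if (n_sibs > config$n_children)
    stop("unrealizable design: sibships need ", n_sibs,
         " children but n_children = ", config$n_children)
  n_singles <- config$n_children - n_sibs

  # children are built group by group; mother/father ids index the pedigree
  child <- 0L; mother_n <- 0L; father_n <- 0L; home_n <- 0L
  mother <- character(0); father <- character(0); home <- character(0)
  pool <- list() # children awaiting a mixed home, with their mother id
  new_home <- function() { home_n <<- home_n + 1L; sprintf("H%03d", home_n) }
  add_child <- function(m, f, h) {
    child <<- child + 1L
    mother[child] <<- m; father[child] <<- f; home[child] <<- h
  }
  for (g in seq_along(full_sizes)) {
    mother_n <- mother_n + 1L; father_n <- father_n + 1L
    m <- sprintf("M%03d", mother_n); f <- sprintf("F%03d", father_n)
    h <- if (full_j[g] >= 2) new_home() else NA_character_
    for (i in seq_len(full_sizes[g]))
      add_child(m, f, if (i <= full_j[g] && !is.na(h)) h else NA_character_)
  }
  for (g in seq_along(half_sizes)) {
    mother_n <- mother_n + 1L
    m <- sprintf("M%03d", mother_n)
    h <- if (half_j[g] >= 2) new_home() else NA_character_
    for (i in seq_len(half_sizes[g])) {
      father_n <- father_n + 1L
      add_child(m, sprintf("F%03d", father_n),
                if (i <= half_j[g] && !is.na(h)) h else NA_character_)
    }
  }
  for (i in seq_len(n_singles)) {
    mother_n <- mother_n + 1L; father_n <- father_n + 1L
    add_child(sprintf("M%03d", mother_n), sprintf("F%03d", father_n),
              NA_character_)
  }

  unplaced <- which(is.na(home))
  homes_left <- config$n_homes - home_n
  extras <- length(unplaced) - homes_left
  if (extras < 0)
    stop("unrealizable design: ", length(unplaced),
         " children left for ", homes_left, " homes")
  mixed_sizes <- allocate_mixed_homes(p["unrelated_together"], extras,
                                      max_homes = homes_left)
  if (home_n + length(mixed_sizes) +
      (length(unplaced) - sum(mixed_sizes)) != config$n_homes)
    stop("unrealizable design: household count does not close")

  # interleave the unplaced children by mother so consecutive children have
  # distinct mothers, then fill the mixed homes from the head of that list
  grp <- split(unplaced, mother[unplaced])
  grp <- grp[order(-lengths(grp))]
  maxlen <- max(lengths(grp))
  inter <- unlist(lapply(seq_len(maxlen), function(r)
    unlist(lapply(grp, function(g) if (length(g) >= r) g[r] else NULL))),
    use.names = FALSE)
  pos <- 1
  for (s in mixed_sizes) {
    members <- inter[pos:(pos + s - 1)]
    if (anyDuplicated(mother[members]))
      stop("unrealizable design: could not avoid co-housing siblings")
    h <- new_home()
    home[members] <- h
    pos <- pos + s
  }
  for (i in inter[seq(pos, length.out = length(inter) - pos + 1)])
    home[i] <- new_home()

  ids <- sprintf("C%03d", seq_len(child))
  md <- with_seed(seed, {
    data.frame(child_id = ids,
               home_id = home,
               sex = ifelse(stats::runif(child) < config$sex_ratio, 1L, 2L),
               age_years = exp(stats::runif(child, log(config$age_range[1]),
                                            log(config$age_range[2]))),
               bmi_z = stats::rnorm(child),
               depth = round(stats::runif(child, config$depth_range[1],
                                          config$depth_range[2])),
               stringsAsFactors = FALSE)
  })
  K <- diag(1, child)
  same_mother <- outer(mother, mother, `==`)
  same_father <- outer(father, father, `==`)
  K[same_mother & same_father] <- 0.5
  K[same_mother & !same_father] <- 0.25
  diag(K) <- 1
  dimnames(K) <- list(ids, ids)
  depth <- stats::setNames(md$depth, ids)
  metadata <- sample_metadata(md[c("child_id", "home_id", "sex",
                                   "age_years", "bmi_z")])
  K_true <- pairwise_matrix(K, kind = "relatedness")
  census <- pair_census(pair_records(metadata, K_true))
  if (!identical(unname(census), unname(p)))
    stop("internal error: realized census ",
         paste(census, collapse = "/"), " != requested ",
         paste(p, collapse = "/"))
  structure(list(metadata = metadata, K_true = K_true,
                 pedigree = data.frame(child_id = ids, mother = mother,
                                       father = father,
                                       stringsAsFactors = FALSE),
                 depth = depth[order(ids)],
                 config = config, seed = seed),
            class = "synthetic_design")
}

#' @export
print.synthetic_design <- function(x, ...) {
  cat(sprintf("synthetic_design: %d children, %d homes\n",
              nrow(x$metadata), length(unique(x$metadata$home_id))))
  print(pair_census(pair_records(x$metadata, x$K_true)))
  invisible(x)
}

#' Simulate SNP genotypes down the pedigree and estimate relatedness
#'
#' Draws biallelic founder genotypes at minor allele frequencies uniform in
#' `maf_range`, transmits alleles through the pedigree (each parent passes
#' an allele with probability dosage/2, independently per unlinked marker),
#' and estimates pairwise relatedness with the Queller-Goodnight moment
#' estimator (symmetrised, sample allele frequencies).
#'
#' @param design a [simulate_design()] result.
#' @param n_snps number of markers (study setting: 2,500).
#' @param maf_range founder minor-allele-frequency range.
#' @param seed integer seed.
#' @return list: `K_hat` (estimated relatedness, [pairwise_matrix]),
#'   `genotypes` (children x SNPs dosage matrix).
#' @export
simulate_genotypes_and_relatedness <- function(design, n_snps = 2500,
                                               maf_range = c(0.1, 0.5),
                                               seed = 1) {
  stopifnot(inherits(design, "synthetic_design"))
  if (n_snps < 100) warning("fewer than 100 SNPs gives unstable relatedness estimates")
  ped <- design$pedigree
  ped <- ped[order(ped$child_id), ]
  founders <- unique(c(ped$mother, ped$father))
  G <- with_seed(seed, {
    p <- stats::runif(n_snps, maf_range[1], maf_range[2])
    Gf <- matrix(stats::rbinom(length(founders) * n_snps, 2, rep(p, each = length(founders))),
                 nrow = length(founders), dimnames = list(founders, NULL))
    gm <- Gf[ped$mother, , drop = FALSE]
    gf <- Gf[ped$father, , drop = FALSE]
    m_allele <- matrix(stats::rbinom(length(gm), 1, gm / 2), nrow = nrow(gm))
    f_allele <- matrix(stats::rbinom(length(gf), 1, gf / 2), nrow = nrow(gf))
    m_allele + f_allele
  })
  rownames(G) <- ped$child_id
  K_hat <- queller_goodnight(G)
  list(K_hat = pairwise_matrix(K_hat, kind = "relatedness"), genotypes = G)
}

#' Queller-Goodnight pairwise relatedness from SNP dosages
#'
#' Symmetrised moment estimator over biallelic markers using sample allele
#' frequencies; monomorphic markers are dropped. The diagonal is set to 1.
#'
#' @param G children x SNPs dosage matrix (0/1/2).
#' @return symmetric relatedness matrix.
#' @export
queller_goodnight <- function(G) {
  p <- colMeans(G) / 2
  keep <- p > 0 & p < 1
  G <- G[, keep, drop = FALSE]
  p <- p[keep]
  L <- ncol(G)
  n <- nrow(G)
  # similarity: cross-allele identity count, 0.5 * (ax*ay + bx*by)
  S <- 0.5 * (tcrossprod(G) + tcrossprod(2 - G))
  # per-individual sums of own-allele frequencies and homozygosity
  a <- drop(G %*% p + (2 - G) %*% (1 - p))
  hom <- rowSums(G != 1)
  num <- S - a                 # row-indexed numerator sums
  den <- L + hom - a           # per-row denominator sums
  r_dir <- num / den           # r_{x->y} in rows
  r <- (r_dir + t(r_dir)) / 2
  diag(r) <- 1
  dimnames(r) <- list(rownames(G), rownames(G))
  r
}

#' Simulate an ASV count table with known variance components
#'
#' For each ASV the log-scale linear predictor is
#' `eta = beta0 + beta_age * ln(age) + beta_sex * sex + a + h + e + ln(depth)`
#' with `a ~ MVN(0, sigma2_g * K_true)` (kinship-structured), `h` shared
#' within home `~ N(0, sigma2_home)`, `e` iid latent noise
#' `~ N(0, sigma2_resid)`, and counts drawn negative-binomially with
#' dispersion `theta`. ASVs are labelled `heritable` (only `sigma2_g` on),
#' `home` (only `sigma2_home` on) or `null` (both off); baseline
#' log-relative-abundances are spread log-uniformly wide enough that
#' realized prevalence spans singletons (and absent taxa) through
#' ubiquitous taxa, mimicking the long rarity tail of 16S surveys. A
#' synthetic order-level taxonomy is attached.
#'
#' @param design a [simulate_design()] result.
#' @param n_asvs number of ASVs.
#' @param class_mix proportions for classes `heritable`, `home`, `null`.
#' @param sigma2_g,sigma2_home latent effect variances for the "on" classes.
#' @param sigma2_resid iid latent residual variance (all ASVs).
#' @param beta_age,beta_sex fixed-effect sizes.
#' @param baseline_range range of log baseline relative abundance.
#' @param theta_range per-ASV NB dispersion drawn log-uniformly in this range.
#' @param seed integer seed.
#' @return list: `table` ([asv_table] with taxonomy and the design depths),
#'   `params` (per-ASV generating parameters and class labels).
#' @export
simulate_counts <- function(design, n_asvs = 200,
                            class_mix = c(heritable = 0.25, home = 0.25,
                                          null = 0.5),
                            sigma2_g = 1, sigma2_home = 1,
                            sigma2_resid = 0.5,
                            beta_age = 0.1, beta_sex = 0,
                            baseline_range = log(c(2e-7, 5e-3)),
                            theta_range = c(0.5, 5), seed = 1) {
  stopifnot(inherits(design, "synthetic_design"))
  if (sigma2_g < 0 || sigma2_home < 0 || sigma2_resid < 0)
    stop("variances must be non-negative")
  if (any(theta_range <= 0)) stop("theta must be positive")
  md <- design$metadata
  n <- nrow(md)
  K <- design$K_true$values
  Lk <- t(chol(K + diag(1e-8, n)))
  homes <- factor(md$home_id)
  out <- with_seed(seed, {
    classes <- sample(names(class_mix), n_asvs, replace = TRUE,
                      prob = class_mix)
    beta0 <- stats::runif(n_asvs, baseline_range[1], baseline_range[2])
    theta <- exp(stats::runif(n_asvs, log(theta_range[1]), log(theta_range[2])))
    counts <- matrix(0L, n, n_asvs)
    for (j in seq_len(n_asvs)) {
      sg <- if (classes[j] == "heritable") sigma2_g else 0
      sh <- if (classes[j] == "home") sigma2_home else 0
      a <- if (sg > 0) sqrt(sg) * drop(Lk %*% stats::rnorm(n)) else 0
      h <- if (sh > 0) sqrt(sh) * stats::rnorm(nlevels(homes))[homes] else 0
      e <- if (sigma2_resid > 0) stats::rnorm(n, sd = sqrt(sigma2_resid)) else 0
      eta <- beta0[j] + beta_age * log(md$age_years) + beta_sex * md$sex +
        a + h + e + log(design$depth)
      counts[, j] <- stats::rnbinom(n, size = theta[j], mu = exp(pmin(eta, 25)))
    }
    list(classes = classes, beta0 = beta0, theta = theta, counts = counts)
  })
  asv_ids <- sprintf("ASV%04d", seq_len(n_asvs))
  dimnames(out$counts) <- list(md$child_id, asv_ids)
  taxonomy <- synthetic_taxonomy(asv_ids, seed = derive_seed(seed, "taxonomy"))
  params <- data.frame(asv_id = asv_ids, class = out$classes,
                       sigma2_g = ifelse(out$classes == "heritable", sigma2_g, 0),
                       sigma2_home = ifelse(out$classes == "home", sigma2_home, 0),
                       sigma2_resid = sigma2_resid,
                       beta0 = out$beta0, theta = out$theta,
                       stringsAsFactors = FALSE)
  list(table = asv_table(out$counts, depth = design$depth, taxonomy = taxonomy),
       params = params)
}

#' Simulate presence/absence indicators on the logit scale
#'
#' Analogue of [simulate_counts()] for presence models: per ASV,
#' `logit P(present) = alpha0 + beta_age ln(age) + beta_sex sex + a + h + e`
#' (no sequencing-depth offset).
#'
#' @inheritParams simulate_counts
#' @param alpha0_range range of the per-ASV logit intercept.
#' @return list: `presence` (children x ASVs 0/1 matrix), `params`.
#' @export
simulate_presence <- function(design, n_asvs = 200,
                              class_mix = c(heritable = 0.25, home = 0.25,
                                            null = 0.5),
                              sigma2_g = 1, sigma2_home = 1,
                              sigma2_resid = 0.5,
                              beta_age = 0, beta_sex = 0,
                              alpha0_range = c(-1.5, 1.5), seed = 1) {
  stopifnot(inherits(design, "synthetic_design"))
  md <- design$metadata
  n <- nrow(md)
  K <- design$K_true$values
  Lk <- t(chol(K + diag(1e-8, n)))
  homes <- factor(md$home_id)
  out <- with_seed(seed, {
    classes <- sample(names(class_mix), n_asvs, replace = TRUE, prob = class_mix)
    alpha0 <- stats::runif(n_asvs, alpha0_range[1], alpha0_range[2])
    pres <- matrix(0L, n, n_asvs)
    for (j in seq_len(n_asvs)) {
      sg <- if (classes[j] == "heritable") sigma2_g else 0
      sh <- if (classes[j] == "home") sigma2_home else 0
      a <- if (sg > 0) sqrt(sg) * drop(Lk %*% stats::rnorm(n)) else 0
      h <- if (sh > 0) sqrt(sh) * stats::rnorm(nlevels(homes))[homes] else 0
      e <- if (sigma2_resid > 0) stats::rnorm(n, sd = sqrt(sigma2_resid)) else 0
      eta <- alpha0[j] + beta_age * log(md$age_years) + beta_sex * md$sex + a + h + e
      pres[, j] <- stats::rbinom(n, 1, stats::plogis(eta))
    }
    list(classes = classes, alpha0 = alpha0, pres = pres)
  })
  asv_ids <- sprintf("ASV%04d", seq_len(n_asvs))
  dimnames(out$pres) <- list(md$child_id, asv_ids)
  list(presence = out$pres,
       params = data.frame(asv_id = asv_ids, class = out$classes,
                           sigma2_g = ifelse(out$classes == "heritable", sigma2_g, 0),
                           sigma2_home = ifelse(out$classes == "home", sigma2_home, 0),
                           sigma2_resid = sigma2_resid,
                           alpha0 = out$alpha0, stringsAsFactors = FALSE))
}

# Synthetic order-level taxonomy: common gut orders with realistic skew.
synthetic_taxonomy <- function(asv_ids, seed = 1) {
  orders <- c(Clostridiales = 0.55, Bacteroidales = 0.20,
              Bifidobacteriales = 0.06, Lactobacillales = 0.06,
              Erysipelotrichales = 0.05, Enterobacterales = 0.04,
              Coriobacteriales = 0.04)
  ord <- with_seed(seed,
    sample(names(orders), length(asv_ids), replace = TRUE, prob = orders))
  phylum <- c(Clostridiales = "Firmicutes", Bacteroidales = "Bacteroidota",
              Bifidobacteriales = "Actinobacteriota",
              Lactobacillales = "Firmicutes",
              Erysipelotrichales = "Firmicutes",
              Enterobacterales = "Proteobacteria",
              Coriobacteriales = "Actinobacteriota")
  data.frame(asv_id = asv_ids, kingdom = "Bacteria",
             phylum = phylum[ord], class = NA_character_, order = ord,
             family = NA_character_, genus = NA_character_,
             row.names = NULL, stringsAsFactors = FALSE)
}
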