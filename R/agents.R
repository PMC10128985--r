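# Agent behaviour. Mobile agents live in plain data frames inside the
# simulation state environment (see engine.R) and each type's per-tick update
# is vectorised over the whole population. Co-occupancy of a pixel is allowed,
# so within-type updates are synchronous; the order of the four type phases is
# shuffled every tick from the run RNG.
#
# Satellite-cell lifecycle stages (sc$stage):
#   0 quiescent (on a fibre-border niche pixel)
#   1 activating (72-tick delay running)
#   2 active (chemotactic, can divide, can differentiate)
#   3 myoblast (seeks a repair site)
#   4 fusing (fusion timer running at a claimed site)

#' Initialise the mobile agent populations
#'
#' Seeds 30 neutrophils and 30 macrophages (all M1) on random ECM pixels,
#' `round(0.08 * 5 * n_fibres)` quiescent satellite cells on fibre-border
#' pixels (the 0.08 SC-per-fibre density for 10 um sections scaled to the
#' 50 um slice; 12 for the default 30-fibre tissue), and 21 fibroblasts on
#' random ECM pixels.
#'
#' @param geom a [tissue_geometry()].
#' @param seed RNG seed (placements are deterministic given the seed).
#' @param config optional [sim_config()] supplying the seeding counts.
#' @return List of data frames `neutrophils`, `macrophages`,
#'   `satellite_cells`, `fibroblasts`; positions are linear pixel indices in
#'   column `idx` with 1-based `row`/`col` alongside.
#' @export
init_agents <- function(geom, seed = 1L, config = sim_config()) {
  ecm <- which(geom$label == -1L)
  if (length(ecm) == 0L) stop("geometry has no ECM pixels to seed agents on")
  border <- border_pixel_idx(geom)
  if (length(border) == 0L) stop("geometry has no fibre-border pixels")
  n_sc <- as.integer(round(config$sc_per_fibre * length(geom$fibre_ids)))
  nr <- nrow(geom$label)
  with_seed(seed, {
    pick <- function(pool, n) pool[sample.int(length(pool), n, replace = n > length(pool))]
    n_n <- config$baseline_neutrophils
    n_m <- config$baseline_macrophages
    n_f <- config$baseline_fibroblasts
    neut <- data.frame(idx = pick(ecm, n_n), target = rep(NA_integer_, n_n),
                       timer = rep(NA_integer_, n_n), idle = rep(0L, n_n))
    mac <- data.frame(idx = pick(ecm, n_m), target = rep(NA_integer_, n_m),
                      timer = rep(NA_integer_, n_m), idle = rep(0L, n_m),
                      phen = rep(1L, n_m), nphago = rep(0L, n_m))
    sc <- data.frame(idx = pick(border, n_sc), stage = rep(0L, n_sc),
                     timer = rep(0L, n_sc), dwell = rep(0L, n_sc),
                     cool = rep(0L, n_sc), lowhgf = rep(0L, n_sc),
                     site = rep(NA_integer_, n_sc), act_age = rep(0L, n_sc))
    fib <- data.frame(idx = pick(ecm, n_f))
    out <- list(neutrophils = neut, macrophages = mac,
                satellite_cells = sc, fibroblasts = fib)
    lapply(out, function(df) {
      rc <- idx_to_rc(df$idx, nr)
      cbind(df, row = rc[, 1L], col = rc[, 2L])
    })
  })
}

#' Recompute the fibre outline after repair
#'
#' When no satellite cells remain active after a damage episode, the fibre
#' border set is recomputed from the current fibril/ECM adjacency so that
#' fibroblast targeting (and the satellite-cell niche) follow the remodelled
#' outline. With active satellite cells present this is a no-op and the
#' previous outline is returned unchanged.
#'
#' @param geom a [tissue_geometry()] (current, possibly remodelled).
#' @param sc_active_count number of satellite cells in active stages.
#' @param previous previously computed outline (matrix of `row`, `col`);
#'   returned as-is when `sc_active_count > 0`.
#' @return Border pixel coordinate matrix (`row`, `col`).
#' @export
remodel_fibre_outline <- function(geom, sc_active_count, previous = NULL) {
  if (sc_active_count > 0L && !is.null(previous)) return(previous)
  if (sc_active_count > 0L) return(fibre_border_pixels(geom))
  fibre_border_pixels(geom)
}

#' Fusion-timer draw
#'
#' Whole number of ticks a myoblast remains at a repair site before fusing,
#' uniform on `{3, ..., 24}` (the 12-48 h alignment/adhesion/fusion window at
#' the model's tick resolution).
#'
#' @param n number of draws.
#' @param min,max inclusive bounds.
#' @return Integer vector.
#' @export
rfusion_timer <- function(n, min = 3L, max = 24L) {
  min + sample.int(max - min + 1L, n, replace = TRUE) - 1L
}

# ---- internal per-tick phases (st is the state environment) -----------------

# damaged-element masks (state 1 only: removed elements are debris already gone)
.mask_damaged <- function(st) {
  dmg <- st$fstate == 1L
  dmg[is.na(dmg)] <- FALSE
  dmgE <- st$estate == 1L
  dmgE[is.na(dmgE)] <- FALSE
  dmg | dmgE
}

# shared target acquisition + phagocytosis for neutrophils and macrophages;
# returns indices of agents in contact with damage (cytokine source positions)
.engage <- function(st, ag, dmg) {
  cfg <- st$cfg
  valid <- !is.na(ag$target)
  valid[valid] <- dmg[ag$target[valid]]
  ag$target[!valid] <- NA_integer_
  ag$timer[!valid] <- NA_integer_

  need <- which(is.na(ag$target))
  if (length(need) > 0L) {
    nbh <- cbind(ag$idx[need], neighbour_idx(ag$idx[need], st$nr, st$nc))
    cand <- matrix(FALSE, length(need), 9L)
    ok <- !is.na(nbh)
    cand[ok] <- dmg[nbh[ok]]
    has <- rowSums(cand) > 0L
    if (any(has)) {
      score <- matrix(-1, length(need), 9L)
      score[cand] <- stats::runif(sum(cand))
      pick <- max.col(score, ties.method = "first")
      ag$target[need[has]] <- nbh[cbind(which(has), pick[has])]
    }
  }
  engaged <- which(!is.na(ag$target))
  if (length(engaged) > 0L) {
    tgt <- ag$target[engaged]
    hits <- table(tgt)
    ti <- as.integer(names(hits))
    st$integ[ti] <- pmax(st$integ[ti] - cfg$integrity_decrement * as.vector(hits), 0)
    # the phagocytosis gate: timers run once the element is broken down
    broken <- st$integ[tgt] <= cfg$clearance_threshold
    newt <- engaged[broken & is.na(ag$timer[engaged])]
    if (length(newt) > 0L)
      ag$timer[newt] <- ifelse(st$lab[ag$target[newt]] > 0L,
                               cfg$phago_ticks_fibril, cfg$phago_ticks_ecm)
    run <- engaged[broken]
    ag$timer[run] <- ag$timer[run] - 1L
    done <- run[!is.na(ag$timer[run]) & ag$timer[run] <= 0L]
    if (length(done) > 0L) {
      rem <- unique(ag$target[done])
      fibr <- rem[st$lab[rem] > 0L]
      ecmr <- rem[st$lab[rem] == -1L]
      if (length(fibr) > 0L) {
        st$fstate[fibr] <- 2L
        st$removed_tick[fibr] <- st$tick
      }
      if (length(ecmr) > 0L) {
        st$estate[ecmr] <- 2L
        st$coll[ecmr] <- 0
      }
      st$dmg_dirty <- TRUE
      ag$completed <- ag$completed | seq_len(nrow(ag)) %in% done
      ag$target[done] <- NA_integer_
      ag$timer[done] <- NA_integer_
    }
  }
  list(ag = ag, contact = engaged)
}

# one greedy downhill step on a distance map for each agent (ties random);
# agents stay put when no neighbour strictly improves
.descend_step <- function(idx, dmap, nr, nc) {
  nb <- neighbour_idx(idx, nr, nc)
  dv <- matrix(Inf, length(idx), 8L)
  ok <- !is.na(nb)
  vv <- dmap[nb[ok]]
  vv[is.na(vv)] <- Inf
  dv[ok] <- vv
  own <- dmap[idx]
  own[is.na(own)] <- Inf
  pick <- row_argmin_random(dv)
  best <- dv[cbind(seq_along(idx), pick)]
  mv <- best < own
  idx[mv] <- nb[cbind(which(mv), pick[mv])]
  idx
}

.step_neutrophils <- function(st) {
  cfg <- st$cfg
  ag <- st$neut
  dmg <- .mask_damaged(st)
  any_dmg <- any(dmg)
  if (!any_dmg && nrow(ag) <= cfg$baseline_neutrophils) return(invisible())

  ag$completed <- rep(FALSE, nrow(ag))
  if (any_dmg) {
    res <- .engage(st, ag, dmg)
    ag <- res$ag
    st$src_neut <- c(st$src_neut, ag$idx[res$contact])
    # movement: free agents step to the lowest-collagen Moore neighbour
    free <- which(is.na(ag$target))
    if (length(free) > 0L) {
      nb <- neighbour_idx(ag$idx[free], st$nr, st$nc)
      cv <- matrix(Inf, length(free), 8L)
      ok <- !is.na(nb)
      cv[ok] <- st$ceff[nb[ok]]
      pick <- row_argmin_random(cv)
      mv <- is.finite(cv[cbind(seq_along(free), pick)])
      ag$idx[free[mv]] <- nb[cbind(which(mv), pick[mv])]
    }
    # proliferation by agents that have encountered damage, in areas of
    # high TNF-a + IL-6, limited by local crowding
    lvl <- st$fields$layers$TNF[ag$idx] + st$fields$layers$IL6[ag$idx]
    dens <- table(ag$idx)
    in_contact <- seq_len(nrow(ag)) %in% res$contact
    elig <- which(in_contact & lvl > cfg$neut_prolif_threshold &
                  as.vector(dens[as.character(ag$idx)]) < cfg$crowding_cap)
    if (length(elig) > 0L) {
      born <- elig[stats::runif(length(elig)) < cfg$neut_prolif_prob]
      if (length(born) > 0L) {
        pos <- .spawn_positions(st, ag$idx[born])
        ag <- rbind(ag, data.frame(idx = pos, target = NA_integer_,
                                   timer = NA_integer_, idle = 0L,
                                   completed = FALSE))
      }
    }
  }
  ag <- .resolve(st, ag, cfg$baseline_neutrophils)
  ag$completed <- NULL
  st$neut <- ag
  invisible()
}

.step_macrophages <- function(st) {
  cfg <- st$cfg
  ag <- st$mac
  dmg <- .mask_damaged(st)
  any_dmg <- any(dmg)
  if (!any_dmg && nrow(ag) <= cfg$baseline_macrophages) return(invisible())

  ag$completed <- rep(FALSE, nrow(ag))
  if (any_dmg) {
    res <- .engage(st, ag, dmg)
    ag <- res$ag
    # the M1/M2 phenotype switch is permanent after the first phagocytosis
    ag$nphago <- ag$nphago + as.integer(ag$completed)
    ag$phen[ag$nphago >= 1L] <- 2L
    st$src_mac <- c(st$src_mac, ag$idx[intersect(res$contact,
                                                 which(ag$phen == 1L))])
    # movement: free agents descend the damage distance map
    free <- which(is.na(ag$target))
    if (length(free) > 0L) {
      idx <- ag$idx[free]
      for (s in seq_len(cfg$mac_speed))
        idx <- .descend_step(idx, st$dmap_damage, st$nr, st$nc)
      ag$idx[free] <- idx
    }
    # recruitment under persistent damage: macrophages in contact with
    # damage expand the pool; newcomers enter pro-inflammatory (M1)
    if (st$tick >= cfg$mac_prolif_window) {
      dens <- table(ag$idx)
      elig <- res$contact[as.vector(dens[as.character(ag$idx[res$contact])]) <
                          cfg$crowding_cap]
      if (length(elig) > 0L) {
        born <- elig[stats::runif(length(elig)) < cfg$mac_prolif_prob]
        if (length(born) > 0L) {
          pos <- .spawn_positions(st, ag$idx[born])
          ag <- rbind(ag, data.frame(idx = pos, target = NA_integer_,
                                     timer = NA_integer_, idle = 0L,
                                     phen = 1L, nphago = 0L, completed = FALSE))
        }
      }
    }
  }
  ag <- .resolve(st, ag, cfg$baseline_macrophages)
  ag$completed <- NULL
  st$mac <- ag
  invisible()
}

# resolution of inflammation: agents idle for resolution_idle ticks are
# removed, never dropping below the seeded baseline
.resolve <- function(st, ag, baseline) {
  cfg <- st$cfg
  near <- st$dmap_damage[ag$idx]
  is_near <- !is.na(near) & near <= cfg$sense_radius
  ag$idle <- ifelse(is_near, 0L, ag$idle + 1L)
  n <- nrow(ag)
  if (n > baseline) {
    cand <- which(ag$idle >= cfg$resolution_idle)
    k <- min(length(cand), n - baseline)
    if (k > 0L) {
      drop <- cand[order(-ag$idle[cand])][seq_len(k)]
      ag <- ag[-drop, , drop = FALSE]
    }
  }
  ag
}

# spawn adjacent to the parent, on any tissue pixel (random neighbour)
.spawn_positions <- function(st, parent_idx) {
  nb <- neighbour_idx(parent_idx, st$nr, st$nc)
  okm <- matrix(FALSE, length(parent_idx), 8L)
  ok <- !is.na(nb)
  okm[ok] <- st$lab[nb[ok]] != 0L
  score <- matrix(-1, length(parent_idx), 8L)
  score[okm] <- stats::runif(sum(okm))
  pick <- max.col(score, ties.method = "first")
  has <- rowSums(okm) > 0L
  out <- parent_idx
  out[has] <- nb[cbind(which(has), pick[has])]
  out
}

.step_satellite_cells <- function(st) {
  cfg <- st$cfg
  sc <- st$sc
  hgf <- st$fields$layers$HGF
  if (nrow(sc) == 0L) return(invisible())
  # elevated HGF = above its own baseline level at that pixel
  hgf_ratio <- function(idx)
    hgf[idx] / pmax(st$base_layers$HGF[idx], cfg$gradient_eps)
  hgf_high <- function(idx)
    hgf_ratio(idx) > cfg$hgf_activation_rel
  if (all(sc$stage == 0L) && !any(hgf_high(sc$idx)))
    return(invisible())

  # quiescent -> activating in the presence of elevated HGF, with a
  # dose-dependent per-tick rate (stronger elevation recruits faster)
  act <- which(sc$stage == 0L & hgf_high(sc$idx))
  if (length(act) > 0L) {
    p_act <- pmin(1, cfg$sc_activation_gain *
                    (hgf_ratio(sc$idx[act]) - cfg$hgf_activation_rel))
    act <- act[stats::runif(length(act)) < p_act]
  }
  if (length(act) > 0L) {
    sc$stage[act] <- 1L
    sc$timer[act] <- cfg$sc_activation_delay
    sc$act_age[act] <- 0L
    st$cum_sc_activated <- st$cum_sc_activated + length(act)
  }
  # activation delay
  run <- which(sc$stage == 1L)
  if (length(run) > 0L) {
    sc$timer[run] <- sc$timer[run] - 1L
    sc$stage[run[sc$timer[run] <= 0L]] <- 2L
  }

  repair_exists <- any(st$repair_mask)
  work_exists <- any(st$work_mask)

  # active cells: chemotax up HGF + IL-6, divide, differentiate, requiesce
  actv <- which(sc$stage == 2L)
  if (length(actv) > 0L) {
    grad <- hgf + st$fields$layers$IL6
    idx <- sc$idx[actv]
    for (s in seq_len(st$sc_moves)) {
      nb <- neighbour_idx(idx, st$nr, st$nc)
      gv <- matrix(-Inf, length(idx), 8L)
      ok <- !is.na(nb)
      vv <- grad[nb[ok]]
      vv[st$lab[nb[ok]] == 0L] <- -Inf # fibre and ECM media only
      gv[ok] <- vv
      pick <- row_argmax_random(gv)
      best <- gv[cbind(seq_along(idx), pick)]
      mv <- is.finite(best) & best > grad[idx]
      idx[mv] <- nb[cbind(which(mv), pick[mv])]
    }
    sc$idx[actv] <- idx

    high <- hgf_high(sc$idx[actv])
    sc$dwell[actv] <- ifelse(high, sc$dwell[actv] + 1L, 0L)
    sc$lowhgf[actv] <- ifelse(high, 0L, sc$lowhgf[actv] + 1L)
    sc$cool[actv] <- pmax(sc$cool[actv] - 1L, 0L)
    sc$act_age[actv] <- sc$act_age[actv] + 1L

    igf1 <- st$fields$layers$IGF1
    igf1_present <- igf1[sc$idx[actv]] >
      st$base_layers$IGF1[sc$idx[actv]] + cfg$gradient_eps
    div <- actv[sc$dwell[actv] >= cfg$hgf_division_dwell &
                igf1_present & sc$cool[actv] == 0L]
    if (length(div) > 0L) {
      # niche-limited proliferation: division shuts off as the pool
      # approaches the niche ceiling, so very large injuries exhaust the
      # pool instead of expanding it without bound
      pool_cap <- cfg$sc_pool_factor * st$n_sc_seeded
      p_div <- cfg$sc_division_prob * max(0, 1 - nrow(sc) / pool_cap)
      div <- div[stats::runif(length(div)) < p_div]
    }
    if (length(div) > 0L) {
      sc$cool[div] <- cfg$sc_division_cooldown
      symmetric <- stats::runif(length(div)) < 0.5
      st$cum_sc_activated <- st$cum_sc_activated + sum(symmetric)
      kids <- lapply(seq_along(div), function(j) {
        mother <- div[j]
        if (symmetric[j]) {
          # symmetric: two active daughters
          data.frame(idx = .spawn_positions(st, sc$idx[mother]), stage = 2L,
                     timer = 0L, dwell = 0L, cool = cfg$sc_division_cooldown,
                     lowhgf = 0L, site = NA_integer_, act_age = 0L)
        } else {
          # asymmetric: one active stays, one quiescent returns to the niche
          data.frame(idx = .nearest_border(st, sc$idx[mother]), stage = 0L,
                     timer = 0L, dwell = 0L, cool = 0L, lowhgf = 0L,
                     site = NA_integer_, act_age = 0L)
        }
      })
      sc <- rbind(sc, do.call(rbind, kids))
    }

    # differentiation after the proliferative phase of the active stage:
    # on a supra-baseline or rising IGF-1 signal, or -- once the HGF window
    # has closed with repair work still outstanding -- by default, so
    # late-maturing cells commit instead of idling
    igf1_up <- igf1[sc$idx[actv]] >
      st$prev$IGF1[sc$idx[actv]] + cfg$gradient_eps
    committed <- !high & work_exists
    diff <- actv[(igf1_up | igf1_present | committed) &
                 sc$act_age[actv] >= cfg$differentiation_delay]
    sc$stage[diff] <- 3L

    # return to quiescence once HGF has faded and nothing is left to repair
    if (!work_exists) {
      back <- actv[sc$lowhgf[actv] >= cfg$requiescence_idle & sc$stage[actv] == 2L]
      if (length(back) > 0L) {
        sc$stage[back] <- 0L
        sc$idx[back] <- vapply(sc$idx[back], function(p) .nearest_border(st, p),
                               integer(1))
        sc$dwell[back] <- 0L
        sc$lowhgf[back] <- 0L
        sc$act_age[back] <- 0L
      }
    }
  }

  # myoblasts: seek the nearest cleared (removed) site, claim it and draw a
  # fusion timer; while debris is still being cleared they gather at the
  # damage; with no fibril injury left anywhere they fuse at a fibre border
  # (hypertrophy)
  myo <- which(sc$stage == 3L)
  if (length(myo) > 0L) {
    if (repair_exists) {
      idx <- sc$idx[myo]
      for (s in seq_len(st$sc_moves))
        idx <- .descend_step(idx, st$dmap_repair, st$nr, st$nc)
      sc$idx[myo] <- idx
      arrive <- myo[st$repair_mask[sc$idx[myo]] & !st$claimed[sc$idx[myo]]]
      if (length(arrive) > 0L) {
        # one claim per site
        arrive <- arrive[!duplicated(sc$idx[arrive])]
        sc$stage[arrive] <- 4L
        sc$site[arrive] <- sc$idx[arrive]
        sc$timer[arrive] <- rfusion_timer(length(arrive), cfg$fusion_min,
                                          cfg$fusion_max)
        st$claimed[sc$site[arrive]] <- TRUE
      }
    } else if (work_exists) {
      # nothing cleared yet: move toward the damage and wait for debris
      # removal to open fusion sites
      idx <- sc$idx[myo]
      for (s in seq_len(st$sc_moves))
        idx <- .descend_step(idx, st$dmap_damage, st$nr, st$nc)
      sc$idx[myo] <- idx
    } else if (sum(st$fstate == 0L, na.rm = TRUE) <
               (1 + cfg$hypertrophy_limit) * st$initial_fibril) {
      sc <- .hypertrophy_step(st, sc, myo)
    } else {
      # fibres restored beyond the hypertrophy allowance: leftover
      # myoblasts return to the niche as quiescent cells
      sc$stage[myo] <- 0L
      sc$idx[myo] <- vapply(sc$idx[myo],
                            function(p) .nearest_border(st, p), integer(1))
      sc$dwell[myo] <- 0L
      sc$lowhgf[myo] <- 0L
      sc$act_age[myo] <- 0L
    }
  }

  # fusing: on expiry the myoblast's fusion regenerates the local patch of
  # damaged/removed fibrils (the regenerative mirror of the 3x3 necrosis
  # spread); the agent either incorporates into the fibre (consumed) or
  # carries on to the next nearest repair site
  fus <- which(sc$stage == 4L)
  if (length(fus) > 0L) {
    sc$timer[fus] <- sc$timer[fus] - 1L
    done <- fus[sc$timer[fus] <= 0L]
    if (length(done) > 0L) {
      sites <- sc$site[done]
      is_rep <- st$lab[sites] > 0L & !is.na(st$fstate[sites]) &
        st$fstate[sites] %in% c(1L, 2L)
      if (any(is_rep)) {
        s2 <- sites[is_rep]
        r <- st$cfg$repair_patch
        offs <- as.matrix(expand.grid(dr = -r:r, dc = -r:r))
        offs <- offs[!(offs[, 1L] == 0L & offs[, 2L] == 0L), , drop = FALSE]
        patch <- unique(c(s2, as.vector(neighbour_idx(s2, st$nr, st$nc,
                                                      offsets = offs))))
        patch <- patch[!is.na(patch)]
        # the claimed site itself is regenerated whatever its state; the
        # surrounding patch only heals already-cleared (removed) pixels
        heal <- patch[st$lab[patch] > 0L & !is.na(st$fstate[patch]) &
                      st$fstate[patch] == 2L]
        heal <- unique(c(s2, heal))
        st$fstate[heal] <- 0L
        st$integ[heal] <- 1
        st$removed_tick[heal] <- NA_integer_
        st$claimed[heal] <- FALSE
        st$claimed[s2] <- FALSE
        st$dmg_dirty <- TRUE
      }
      # hypertrophy fusion: convert the claimed border-adjacent ECM/EMPTY
      # pixel (and a few safe neighbours) into new fibril tissue of the
      # adjoining fibre
      is_hyp <- !is_rep & st$lab[sites] %in% c(0L, -1L)
      ok <- is_rep
      for (jj in which(is_hyp)) {
        q <- sites[jj]
        budget <- st$cfg$hypertrophy_patch
        queue <- q
        while (length(queue) > 0L && budget > 0L) {
          p <- queue[[1L]]
          queue <- queue[-1L]
          if (!(st$lab[p] %in% c(0L, -1L)) || p %in% st$fibro$idx) next
          nbp <- neighbour_idx(p, st$nr, st$nc)[1L, ]
          nbp <- nbp[!is.na(nbp)]
          fids <- unique(st$lab[nbp])
          fids <- fids[fids > 0L]
          if (length(fids) != 1L) next
          if (st$lab[p] == -1L) {
            st$estate[p] <- NA_integer_
            st$coll[p] <- NA_real_
          }
          st$lab[p] <- fids
          st$fstate[p] <- 0L
          st$integ[p] <- 1
          st$border_dirty <- TRUE
          budget <- budget - 1L
          ok[jj] <- TRUE
          queue <- c(queue, nbp[st$lab[nbp] %in% c(0L, -1L)])
        }
      }
      st$claimed[sites] <- FALSE
      sc$stage[done] <- 3L
      sc$site[done] <- NA_integer_
      p_inc <- ifelse(is_hyp[ok], st$cfg$sc_incorporation_hyper,
                      st$cfg$sc_incorporation_prob)
      consumed <- done[ok][stats::runif(sum(ok)) < p_inc]
      if (length(consumed) > 0L) sc <- sc[-consumed, , drop = FALSE]
    }
  }
  st$sc <- sc
  invisible()
}

# hypertrophy: a myoblast with no repair site left moves to the nearest
# fibre border and fuses there, expanding the border by converting an
# adjacent ECM/EMPTY pixel into new fibril tissue (only where no other fibre
# would become Moore-adjacent). The fusion itself uses the same timer and
# incorporation mechanics as regenerative fusion.
.hypertrophy_step <- function(st, sc, myo) {
  cfg <- st$cfg
  idx <- sc$idx[myo]
  for (s in seq_len(st$sc_moves))
    idx <- .descend_step(idx, st$dmap_border, st$nr, st$nc)
  sc$idx[myo] <- idx
  at_border <- which(!is.na(st$dmap_border[idx]) & st$dmap_border[idx] == 0L)
  for (j in at_border) {
    p <- sc$idx[myo[j]]
    q <- .hypertrophy_site(st, p)
    if (!is.na(q)) {
      sc$stage[myo[j]] <- 4L
      sc$site[myo[j]] <- q
      sc$timer[myo[j]] <- rfusion_timer(1L, cfg$fusion_min, cfg$fusion_max)
      st$claimed[q] <- TRUE
    } else {
      # no convertible pixel here: wander to search the border elsewhere
      nb <- neighbour_idx(p, st$nr, st$nc)[1L, ]
      nb <- nb[!is.na(nb)]
      nb <- nb[st$lab[nb] != 0L]
      if (length(nb) > 0L)
        sc$idx[myo[j]] <- nb[sample.int(length(nb), 1L)]
    }
  }
  sc
}

# a convertible pixel adjacent to the border pixel p of fibre f, or NA
.hypertrophy_site <- function(st, p) {
  f <- st$lab[p]
  if (f <= 0L) return(NA_integer_)
  nb <- neighbour_idx(p, st$nr, st$nc)[1L, ]
  nb <- nb[!is.na(nb)]
  cand <- nb[st$lab[nb] %in% c(0L, -1L) & !st$claimed[nb]]
  cand <- cand[!(cand %in% st$fibro$idx)] # never under a fibroblast
  for (q in cand) {
    nbq <- neighbour_idx(q, st$nr, st$nc)[1L, ]
    nbq <- nbq[!is.na(nbq)]
    lq <- st$lab[nbq]
    if (!any(lq > 0L & lq != f)) return(q)
  }
  NA_integer_
}

# nearest fibre-border pixel (Euclidean, deterministic tie by index order)
.nearest_border <- function(st, p) {
  b <- st$border
  if (length(b) == 0L) return(p)
  rc <- idx_to_rc(p, st$nr)
  brc <- st$border_rc
  d2 <- (brc[, 1L] - rc[1L, 1L])^2 + (brc[, 2L] - rc[1L, 2L])^2
  b[which.min(d2)]
}

.step_fibroblasts <- function(st) {
  cfg <- st$cfg
  ag <- st$fibro
  tgt <- st$fib_target_mask
  any_tgt <- any(tgt)
  il15 <- st$fields$layers$IL15
  tgfb <- st$fields$layers$TGFb
  can_divide <- nrow(ag) < cfg$fibroblast_cap &&
    (sum(il15) > 0 || sum(tgfb) > 0)
  if (!any_tgt && !can_divide && nrow(ag) <= cfg$baseline_fibroblasts)
    return(invisible())

  if (any_tgt && nrow(ag) > 0L) {
    # agents standing on a still-valid target keep working; others repath
    on_tgt <- tgt[ag$idx]
    ag$timer[!on_tgt] <- NA_integer_
    mv <- which(!on_tgt)
    if (length(mv) > 0L) {
      idx <- ag$idx[mv]
      for (s in seq_len(st$fib_moves))
        idx <- .descend_step(idx, st$dmap_fib, st$nr, st$nc)
      ag$idx[mv] <- idx
    }
    # collagen deposition takes time; remodelling a fibril gap takes longer
    on_tgt <- tgt[ag$idx]
    start <- which(on_tgt & is.na(ag$timer))
    if (length(start) > 0L)
      ag$timer[start] <- ifelse(st$lab[ag$idx[start]] > 0L,
                                cfg$fibrosis_ticks, cfg$fib_repair_ticks)
    eng <- which(on_tgt & !is.na(ag$timer))
    if (length(eng) > 0L) {
      ag$timer[eng] <- ag$timer[eng] - 1L
      fin <- eng[ag$timer[eng] <= 0L]
      if (length(fin) > 0L) {
        sites <- unique(ag$idx[fin])
        ecm_sites <- sites[st$lab[sites] == -1L]
        gap_sites <- sites[st$lab[sites] > 0L]
        if (length(ecm_sites) > 0L) {
          # repair: collagen laid down, the ECM element is restored
          st$coll[ecm_sites] <- 1
          st$estate[ecm_sites] <- 0L
          st$integ[ecm_sites] <- 1
        }
        if (length(gap_sites) > 0L) {
          # fibrosis: a long-unrepaired fibril gap is remodelled into ECM
          st$lab[gap_sites] <- -1L
          st$fstate[gap_sites] <- NA_integer_
          st$removed_tick[gap_sites] <- NA_integer_
          st$estate[gap_sites] <- 0L
          st$coll[gap_sites] <- 1
          st$integ[gap_sites] <- 1
          st$border_dirty <- TRUE
          st$dmg_dirty <- TRUE
        }
        ag$timer[fin] <- NA_integer_
        st$fib_dirty <- TRUE
      }
    }
  }

  # division on positive temporal IL-15 and TGF-b gradients, capped at 67
  if (nrow(ag) < cfg$fibroblast_cap) {
    pos <- il15[ag$idx] > st$prev$IL15[ag$idx] + cfg$gradient_eps &
           tgfb[ag$idx] > st$prev$TGFb[ag$idx] + cfg$gradient_eps
    elig <- which(pos)
    if (length(elig) > 0L) {
      born <- elig[stats::runif(length(elig)) < cfg$fib_division_prob]
      born <- utils::head(born, cfg$fibroblast_cap - nrow(ag))
      if (length(born) > 0L) {
        pos2 <- .spawn_ecm_positions(st, ag$idx[born])
        keep <- !is.na(pos2)
        if (any(keep))
          ag <- rbind(ag, data.frame(idx = pos2[keep], target = NA_integer_,
                                     timer = NA_integer_))
      }
    }
  }

  # decay back toward the seeded count once there is nothing to remodel
  if (!any_tgt && nrow(ag) > cfg$baseline_fibroblasts) {
    drop <- which(stats::runif(nrow(ag)) < cfg$fib_decay_prob)
    k <- min(length(drop), nrow(ag) - cfg$baseline_fibroblasts)
    if (k > 0L) ag <- ag[-drop[seq_len(k)], , drop = FALSE]
  }
  st$fibro <- ag
  invisible()
}

# spawn on an adjacent ECM pixel; NA when the parent has none
.spawn_ecm_positions <- function(st, parent_idx) {
  nb <- neighbour_idx(parent_idx, st$nr, st$nc)
  okm <- matrix(FALSE, length(parent_idx), 8L)
  ok <- !is.na(nb)
  okm[ok] <- st$lab[nb[ok]] == -1L
  score <- matrix(-1, length(parent_idx), 8L)
  score[okm] <- stats::runif(sum(okm))
  pick <- max.col(score, ties.method = "first")
  has <- rowSums(okm) > 0L
  out <- rep(NA_integer_, length(parent_idx))
  out[has] <- nb[cbind(which(has), pick[has])]
  out
}

#' Export an agent snapshot as CSV
#'
#' Writes agent positions with columns `agent_type,id,row,col,state` using
#' the on-disk 0-based coordinate convention. Accepts the list returned by
#' [init_agents()].
#'
#' @param agents list of agent data frames (as from [init_agents()]).
#' @param path output CSV path.
#' @param tick tick stamp recorded in the file (default 0).
#' @export
export_agents <- function(agents, path, tick = 0L) {
  rows <- lapply(names(agents), function(type) {
    df <- agents[[type]]
    if (nrow(df) == 0L) return(NULL)
    state <- if (!is.null(df$phen)) ifelse(df$phen == 2L, "M2", "M1")
             else if (!is.null(df$stage))
               c("quiescent", "activating", "active", "myoblast",
                 "fusing")[df$stage + 1L]
             else "resting"
    data.frame(tick = tick, agent_type = type, id = seq_len(nrow(df)),
               row = df$row - 1L, col = df$col - 1L, state = state)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
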