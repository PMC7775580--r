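"""Batch chemistry backend for the molbench R package.

Reads one JSON request from argv[1], writes one JSON response to argv[2].
Every operation is vectorised over a list of SMILES so that a single
process launch amortises over thousands of molecules.

Request:  {"op": <name>, ...op-specific fields...}
Response: op-specific JSON object; fatal problems exit non-zero with a
          message on stderr.
"""

import json
import os
import random
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import BRICS, Crippen, Descriptors, QED, rdMolDescriptors
from rdkit.Chem import rdFingerprintGenerator
from rdkit.Chem.Scaffolds import MurckoScaffold
from rdkit import RDConfig

sys.path.append(os.path.join(RDConfig.RDContribDir, "SA_Score"))
import sascorer  # noqa: E402

RDLogger.DisableLog("rdApp.*")

_MORGAN = rdFingerprintGenerator.GetMorganGenerator(radius=2, fpSize=1024)


def _mol(smiles):
    return Chem.MolFromSmiles(smiles)


def op_parse(req):
    """Validity-checked parse + canonicalisation. Invalid -> canonical None."""
    valid, canonical = [], []
    for smi in req["smiles"]:
        m = _mol(smi) if isinstance(smi, str) else None
        if m is None or m.GetNumAtoms() == 0:
            valid.append(False)
            canonical.append(None)
        else:
            valid.append(True)
            canonical.append(Chem.MolToSmiles(m))
    return {"valid": valid, "canonical": canonical}


def _brics_multiset(m, strip_labels):
    """Per-molecule multiset of BRICS fragments (unlike BRICSDecompose,
    which deduplicates). An uncuttable molecule yields itself."""
    broken = BRICS.BreakBRICSBonds(m)
    frags = Chem.GetMolFrags(broken, asMols=True, sanitizeFrags=False)
    out = []
    for f in frags:
        if strip_labels:
            for a in f.GetAtoms():
                if a.GetAtomicNum() == 0:
                    a.SetIsotope(0)
        out.append(Chem.MolToSmiles(f))
    return out


def _scaffold(m):
    try:
        sc = MurckoScaffold.GetScaffoldForMol(m)
    except Exception:
        return ""
    if sc is None or sc.GetNumAtoms() == 0:
        return ""
    return Chem.MolToSmiles(sc)


def _descriptor_vector(m):
    """Physicochemical descriptor embedding (stand-in for neural-net
    activations in the Frechet-distance machinery)."""
    return [
        Descriptors.MolWt(m),
        Crippen.MolLogP(m),
        sascorer.calculateScore(m),
        QED.qed(m),
        rdMolDescriptors.CalcTPSA(m),
        rdMolDescriptors.CalcNumHBA(m),
        rdMolDescriptors.CalcNumHBD(m),
        rdMolDescriptors.CalcNumRotatableBonds(m),
        rdMolDescriptors.CalcNumAromaticRings(m),
        rdMolDescriptors.CalcNumRings(m),
        rdMolDescriptors.CalcFractionCSP3(m),
        m.GetNumHeavyAtoms(),
    ]


def op_mol_info(req):
    """Per-molecule features for (assumed valid) SMILES. Fields requested
    via req['fields'] from: fp, frags, frags_labeled, scaffold, props,
    descriptors."""
    fields = set(req["fields"])
    out = {f: [] for f in fields}
    for smi in req["smiles"]:
        m = _mol(smi)
        if m is None:
            raise ValueError("mol_info received unparsable SMILES: %r" % smi)
        if "fp" in fields:
            fp = _MORGAN.GetFingerprint(m)
            out["fp"].append(list(fp.GetOnBits()))
        if "frags" in fields:
            out["frags"].append(_brics_multiset(m, strip_labels=True))
        if "frags_labeled" in fields:
            out["frags_labeled"].append(_brics_multiset(m, strip_labels=False))
        if "scaffold" in fields:
            out["scaffold"].append(_scaffold(m))
        if "props" in fields:
            out["props"].append(
                [
                    Descriptors.MolWt(m),
                    Crippen.MolLogP(m),
                    sascorer.calculateScore(m),
                    QED.qed(m),
                ]
            )
        if "descriptors" in fields:
            out["descriptors"].append(_descriptor_vector(m))
    return out


def op_filters(req):
    """Dataset-construction filter rules. Returns, per molecule, the list
    of violated rule labels (empty list = pass)."""
    allowed = set(req["allowed_elements"])
    allowed.add("H")
    max_ring = int(req["max_ring_size"])
    forbid_charges = bool(req["forbid_charges"])
    mcf = [Chem.MolFromSmarts(p) for p in req.get("mcf", [])]
    pains = [Chem.MolFromSmarts(p) for p in req.get("pains", [])]
    for pat, src in [(mcf, "mcf"), (pains, "pains")]:
        if any(p is None for p in pat):
            raise ValueError("uncompilable SMARTS in %s list" % src)
    # optional lead-likeness pre-filters (off unless configured)
    mw_range = req.get("mw_range")
    max_rot = req.get("max_rotatable")
    max_xlogp = req.get("max_xlogp")
    reasons = []
    for smi in req["smiles"]:
        m = _mol(smi)
        if m is None:
            reasons.append(["invalid"])
            continue
        viol = []
        if forbid_charges and any(a.GetFormalCharge() != 0 for a in m.GetAtoms()):
            viol.append("charge")
        if any(a.GetSymbol() not in allowed for a in m.GetAtoms()):
            viol.append("element")
        if any(len(r) > max_ring for r in m.GetRingInfo().AtomRings()):
            viol.append("ring_size")
        if any(m.HasSubstructMatch(p) for p in mcf):
            viol.append("mcf")
        if any(m.HasSubstructMatch(p) for p in pains):
            viol.append("pains")
        if mw_range is not None:
            mw = Descriptors.MolWt(m)
            if mw < mw_range[0] or mw > mw_range[1]:
                viol.append("mw_range")
        if max_rot is not None and \
                rdMolDescriptors.CalcNumRotatableBonds(m) > max_rot:
            viol.append("rotatable_bonds")
        if max_xlogp is not None and Crippen.MolLogP(m) > max_xlogp:
            viol.append("xlogp")
        reasons.append(viol)
    return {"reasons": reasons}


# BRICS attachment-point compatibility, derived from the rule table:
# (label, label) -> bond order of the re-formed bond. Labels 7a/7b share
# isotope 7 (the double-bond rule).
def _brics_compat():
    compat = {}
    for block in BRICS.reactionDefs:
        for a, b, bond in block:
            ia = int(a.rstrip("ab"))
            ib = int(b.rstrip("ab"))
            bt = Chem.BondType.DOUBLE if bond == "=" else Chem.BondType.SINGLE
            compat[(ia, ib)] = bt
            compat[(ib, ia)] = bt
    return compat


_COMPAT = _brics_compat()


def _join(a, b, rng):
    """Join two fragments at a random compatible pair of attachment
    points (BRICS label compatibility decides which pairs may bond and
    with which bond order). Returns None when no compatible pair exists
    or the assembly fails sanitisation."""
    combo = Chem.CombineMols(a, b)
    na = a.GetNumAtoms()
    da = [at.GetIdx() for at in combo.GetAtoms()
          if at.GetAtomicNum() == 0 and at.GetIdx() < na]
    db = [at.GetIdx() for at in combo.GetAtoms()
          if at.GetAtomicNum() == 0 and at.GetIdx() >= na]
    pairs = [(i, j) for i in da for j in db
             if (combo.GetAtomWithIdx(i).GetIsotope(),
                 combo.GetAtomWithIdx(j).GetIsotope()) in _COMPAT]
    if not pairs:
        return None
    i, j = pairs[rng.randrange(len(pairs))]
    bt = _COMPAT[(combo.GetAtomWithIdx(i).GetIsotope(),
                  combo.GetAtomWithIdx(j).GetIsotope())]
    rw = Chem.RWMol(combo)
    ni = rw.GetAtomWithIdx(i).GetNeighbors()[0].GetIdx()
    nj = rw.GetAtomWithIdx(j).GetNeighbors()[0].GetIdx()
    rw.AddBond(ni, nj, bt)
    for idx in sorted((i, j), reverse=True):
        rw.RemoveAtom(idx)
    m = rw.GetMol()
    try:
        Chem.SanitizeMol(m)
    except Exception:
        return None
    return m


def _cap_dummies(m):
    """Remove leftover attachment points; implicit hydrogens fill the
    freed valence."""
    m = Chem.DeleteSubstructs(m, Chem.MolFromSmarts("[#0]"))
    try:
        Chem.SanitizeMol(m)
    except Exception:
        return None
    return m


def op_assemble(req):
    """Assemble each job's fragment list into one molecule.

    jobs: [{"frags": [labeled fragment SMILES], "seed": int}, ...]
    Fragments are joined sequentially at uniformly chosen attachment
    pairs; leftover attachment points are hydrogen-capped. Returns the
    canonical SMILES per job, or None where assembly failed chemically.
    """
    out = []
    attempts = int(req.get("attempts", 10))
    for job in req["jobs"]:
        rng = random.Random(int(job["seed"]))
        base = [_mol(s) for s in job["frags"]]
        if any(m is None for m in base):
            out.append(None)
            continue
        smi = None
        for _ in range(attempts):
            mols = list(base)
            rng.shuffle(mols)
            cur = mols[0]
            for nxt in mols[1:]:
                cur = _join(cur, nxt, rng)
                if cur is None:
                    break
            if cur is None:
                continue
            cur = _cap_dummies(cur)
            if cur is None or cur.GetNumAtoms() == 0:
                continue
            cand = Chem.MolToSmiles(cur)
            # contract: emitted molecules are valid — re-parse to be certain
            if _mol(cand) is not None:
                smi = cand
                break
        out.append(smi)
    return {"smiles": out}


OPS = {
    "parse": op_parse,
    "mol_info": op_mol_info,
    "filters": op_filters,
    "assemble": op_assemble,
}


def main():
    with open(sys.argv[1]) as fh:
        req = json.load(fh)
    op = req.get("op")
    if op not in OPS:
        sys.stderr.write("unknown op: %r\n" % op)
        sys.exit(2)
    out = OPS[op](req)
    with open(sys.argv[2], "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main()
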