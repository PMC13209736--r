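"""RDKit bridge for the mpff package.

Reads a JSON request from argv[1], writes a JSON response to argv[2].
One process call handles a whole batch of SMILES so that interpreter
startup is paid once per library, not once per molecule.

Request:  {"op": <str>, "smiles": [<str>, ...], "pattern": <smarts, optional>}
Ops:
  canonicalize -> {"canonical": [str|None], "error": [str|None]}
  descriptors  -> {"mw": [...], "logp": [...], "hbd": [...], "hba": [...],
                   "error": [...]}
  scaffold     -> {"scaffold": [str|None], "error": [...]}   ("" = acyclic)
  match        -> {"match": [0/1/None], "error": [...]}      (needs pattern)
  featurize    -> {"graphs": [graph|None], "error": [...]}
  profile      -> canonicalize + descriptors + scaffold (+ match if pattern)

Graph: {"num_atoms": n, "atom_features": [[74 floats] * n],
        "src": [...], "dst": [...] (0-based directed edges, both ways),
        "bond_features": [[12 floats] * 2m]}

Atom features (74): element one-hot over 42 symbols + 1 unknown slot,
degree one-hot 0-10, implicit valence one-hot 0-6, formal charge,
radical electrons, hybridization one-hot (SP, SP2, SP3, SP3D, SP3D2),
aromaticity flag, total-H-count one-hot 0-4.
Bond features (12): bond-type one-hot (single, double, triple, aromatic),
conjugation flag, ring flag, stereo one-hot (6 RDKit stereo states).
"""

import json
import sys

from rdkit import Chem
from rdkit import RDLogger
from rdkit.Chem import Crippen, Descriptors, Lipinski
from rdkit.Chem.Scaffolds import MurckoScaffold

RDLogger.DisableLog("rdApp.*")

ELEMENTS = [
    "C", "N", "O", "S", "F", "Si", "P", "Cl", "Br", "Mg", "Na", "Ca", "Fe",
    "As", "Al", "I", "B", "V", "K", "Tl", "Yb", "Sb", "Sn", "Ag", "Pd", "Co",
    "Se", "Ti", "Zn", "H", "Li", "Ge", "Cu", "Au", "Ni", "Cd", "In", "Mn",
    "Zr", "Cr", "Pt", "Hg",
]  # 42 named + 1 unknown slot = 43
HYBRIDIZATIONS = [
    Chem.rdchem.HybridizationType.SP,
    Chem.rdchem.HybridizationType.SP2,
    Chem.rdchem.HybridizationType.SP3,
    Chem.rdchem.HybridizationType.SP3D,
    Chem.rdchem.HybridizationType.SP3D2,
]
BOND_TYPES = [
    Chem.rdchem.BondType.SINGLE,
    Chem.rdchem.BondType.DOUBLE,
    Chem.rdchem.BondType.TRIPLE,
    Chem.rdchem.BondType.AROMATIC,
]
STEREO = [
    Chem.rdchem.BondStereo.STEREONONE,
    Chem.rdchem.BondStereo.STEREOANY,
    Chem.rdchem.BondStereo.STEREOZ,
    Chem.rdchem.BondStereo.STEREOE,
    Chem.rdchem.BondStereo.STEREOCIS,
    Chem.rdchem.BondStereo.STEREOTRANS,
]


def one_hot(value, choices, extra_unknown=False):
    vec = [0.0] * (len(choices) + (1 if extra_unknown else 0))
    try:
        vec[choices.index(value)] = 1.0
    except ValueError:
        if extra_unknown:
            vec[-1] = 1.0
    return vec


def clamped_one_hot(value, max_value):
    # one-hot over 0..max_value with values above clamped to the top slot
    vec = [0.0] * (max_value + 1)
    vec[min(value, max_value)] = 1.0
    return vec


def atom_features(atom):
    return (
        one_hot(atom.GetSymbol(), ELEMENTS, extra_unknown=True)
        + clamped_one_hot(atom.GetDegree(), 10)
        + clamped_one_hot(atom.GetImplicitValence(), 6)
        + [float(atom.GetFormalCharge())]
        + [float(atom.GetNumRadicalElectrons())]
        + one_hot(atom.GetHybridization(), HYBRIDIZATIONS)
        + [1.0 if atom.GetIsAromatic() else 0.0]
        + clamped_one_hot(atom.GetTotalNumHs(), 4)
    )


def bond_features(bond):
    return (
        one_hot(bond.GetBondType(), BOND_TYPES)
        + [1.0 if bond.GetIsConjugated() else 0.0]
        + [1.0 if bond.IsInRing() else 0.0]
        + one_hot(bond.GetStereo(), STEREO)
    )


def parse(smi):
    if not isinstance(smi, str) or smi == "":
        return None, "empty SMILES"
    mol = Chem.MolFromSmiles(smi)
    if mol is None:
        return None, "unparsable SMILES: %s" % smi
    if mol.GetNumAtoms() == 0:
        return None, "no heavy atoms: %s" % smi
    return mol, None


def featurize(mol):
    n = mol.GetNumAtoms()
    af = [atom_features(a) for a in mol.GetAtoms()]
    src, dst, bf = [], [], []
    for bond in mol.GetBonds():
        i, j = bond.GetBeginAtomIdx(), bond.GetEndAtomIdx()
        feats = bond_features(bond)
        src.extend([i, j])
        dst.extend([j, i])
        bf.extend([feats, feats])
    return {
        "num_atoms": n,
        "atom_features": af,
        "src": src,
        "dst": dst,
        "bond_features": bf,
    }


def main():
    with open(sys.argv[1]) as fh:
        req = json.load(fh)
    op = req["op"]
    smiles = req.get("smiles", [])
    pattern = req.get("pattern")
    patt = Chem.MolFromSmarts(pattern) if pattern else None
    if pattern and patt is None:
        json.dump({"fatal": "bad SMARTS pattern: %s" % pattern},
                  open(sys.argv[2], "w"))
        return

    n = len(smiles)
    out = {"error": [None] * n}
    if op in ("canonicalize", "profile"):
        out["canonical"] = [None] * n
    if op in ("descriptors", "profile"):
        out["mw"] = [None] * n
        out["logp"] = [None] * n
        out["hbd"] = [None] * n
        out["hba"] = [None] * n
    if op in ("scaffold", "profile"):
        out["scaffold"] = [None] * n
    if op == "match" or (op == "profile" and patt is not None):
        out["match"] = [None] * n
    if op == "featurize":
        out["graphs"] = [None] * n

    for k, smi in enumerate(smiles):
        mol, err = parse(smi)
        if mol is None:
            out["error"][k] = err
            continue
        if "canonical" in out:
            out["canonical"][k] = Chem.MolToSmiles(mol)
        if "mw" in out:
            out["mw"][k] = Descriptors.MolWt(mol)
            out["logp"][k] = Crippen.MolLogP(mol)
            out["hbd"][k] = Lipinski.NumHDonors(mol)
            out["hba"][k] = Lipinski.NumHAcceptors(mol)
        if "scaffold" in out:
            scaf = MurckoScaffold.GetScaffoldForMol(mol)
            out["scaffold"][k] = (
                Chem.MolToSmiles(scaf) if scaf.GetNumAtoms() > 0 else ""
            )
        if "match" in out:
            out["match"][k] = 1 if mol.HasSubstructMatch(patt) else 0
        if "graphs" in out:
            out["graphs"][k] = featurize(mol)

    with open(sys.argv[2], "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main()
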