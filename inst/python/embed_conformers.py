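"""Deterministic conformer embedding (RDKit ETKDG).

Reads a tab-separated SMILES table (smiles, id), embeds up to --max-confs
conformers per molecule with a fixed random seed and RMSD-based pruning,
and writes one SDF record per conformer (records of one molecule share
its id as title).  Molecules that fail to embed are reported on stderr
as 'EMBED_FAIL <id>' and skipped.
"""

import argparse
import sys

from rdkit import Chem
from rdkit.Chem import AllChem
from rdkit import RDLogger

RDLogger.DisableLog("rdApp.*")


def main():
    ap = argparse.ArgumentParser()
    ap.add_argument("--smi", required=True)
    ap.add_argument("--out", required=True)
    ap.add_argument("--max-confs", type=int, default=200)
    ap.add_argument("--seed", type=int, default=1)
    ap.add_argument("--prune-rms", type=float, default=0.5)
    args = ap.parse_args()

    writer = Chem.SDWriter(args.out)
    writer.SetKekulize(True)
    with open(args.smi) as fh:
        for line in fh:
            fields = line.split()
            if not fields:
                continue
            smi = fields[0]
            mol_id = fields[1] if len(fields) > 1 else smi
            mol = Chem.MolFromSmiles(smi)
            if mol is None:
                sys.stderr.write("EMBED_FAIL %s\n" % mol_id)
                continue
            mol = Chem.AddHs(mol)
            params = AllChem.ETKDGv3()
            params.randomSeed = args.seed
            params.pruneRmsThresh = args.prune_rms
            conf_ids = AllChem.EmbedMultipleConfs(mol, numConfs=args.max_confs,
                                                  params=params)
            if len(conf_ids) == 0:
                sys.stderr.write("EMBED_FAIL %s\n" % mol_id)
                continue
            AllChem.MMFFOptimizeMoleculeConfs(mol, maxIters=200)
            mol.SetProp("_Name", mol_id)
            for cid in conf_ids:
                writer.write(mol, confId=cid)
    writer.close()


if __name__ == "__main__":
    main()
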